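---
title: "Converting neurosurgical imaging workups to DICOM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting neurosurgical imaging workups to DICOM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Research neuroimaging pipelines produce their results as NIfTI volumes
(structural images, statistical maps, manually drawn masks) and, for
tractography, as MRtrix `.tck` streamline files.  Commercial surgical
planning and navigation suites, by contrast, ingest DICOM.  Screenshots
bridge the gap poorly: they freeze a handful of views and cannot be rotated,
re-sliced, or toggled during surgery.  `dicomnav` converts a complete,
coregistered workup into DICOM objects that behave inside a navigation
suite as if they had been created there — volumes as MR image series,
label maps as Segmentation (SEG) objects with one colored segment per
structure, and streamline bundles as Surface Segmentation objects whose
polylines can be rendered as true 3D tracts.

Three principles shape every design decision below:

1. **The converter never alters spatial data.**  No resampling, no
   reorientation to canonical axes, no coregistration (and no checking of
   coregistration — inputs are trusted to be aligned, exactly as the
   upstream pipeline left them).
2. **Failure must be loud.**  Data destined for an operating theatre must
   never be silently truncated, rounded or rearranged; every ambiguous
   input is an error, not a guess.
3. **Conversions are reproducible.**  Given a seed and a fixed clock, two
   runs produce byte-identical output, which makes audits and regression
   testing possible.

## The conversion model

One run is one *conversion context*.  It mints a single frame-of-reference
UID that every emitted object carries, which is what tells the receiving
workstation that all the objects live in one spatial coordinate system and
may be fused.  Patient, study and institution attributes are copied from a
*template* DICOM file — typically one of the files from the session being
analysed — through a closed whitelist (patient name/ID/birth date/sex,
study date/time/description, accession number, institution, referring
physician, study UID).  Nothing else is propagated: copying acquisition
parameters onto derived images would misdescribe them, and copying pixel
data or series UIDs would collide with the originals.  By default the
template's study UID is reused so converted objects attach to the original
study in the patient record; `--new-study-uid` mints a fresh study
instead, for sites that prefer the converted workup kept separate.

### Volumes: NIfTI to classic MR series

NIfTI stores a voxel array plus a 4x4 affine mapping voxel indices to
world RAS (right-anterior-superior) millimetres; DICOM describes the same
grid as per-slice plane origins and row/column direction cosines in LPS
(left-posterior-superior) millimetres.  The conversion negates the first
two world axes and decomposes the affine: column norms give the spacings,
normalised columns give the direction cosines, and the translation plus
k-steps along the third column give the per-slice origins.  Index
`(0,0,0)` is the centre of the first voxel in both conventions, so no
half-voxel shift appears.  Three cases are handled explicitly:

* **Sheared grids** (voxel axes not orthogonal, `|dot|` of unit axes
  above 1e-4) are refused.  DICOM's image-plane model cannot represent
  shear without resampling, and principle 1 forbids resampling.
* **Left-handed grids** (slice axis opposing the row x column normal) are
  exported with the in-memory slice order reversed and the plane origins
  reversed to match, a pure relabelling that moves no sample off its
  world-space position.  The voxel-centre agreement between the affine
  path and the emitted geometry is the property the test suite measures;
  it holds to ~1e-8 mm, against a stated tolerance of 1e-3 mm.
* **4D inputs** (fMRI time series, raw diffusion volumes) are refused
  with an explicit message; a trailing singleton dimension is squeezed.

Classic single-frame MR Image Storage was chosen over Enhanced MR because
single-frame series are what navigation suites most reliably import.
Intensities are stored as unsigned 16-bit with a rescale slope/intercept.
Integer-valued volumes with range at most 65535 use slope 1 and intercept
equal to the minimum, so ordinary integer data survives exactly; other
data is mapped min to 0, max to 65535 (slope = range/65535), bounding the
decode error by slope/2.  A constant volume stores zeros with the constant
as intercept.  NaN voxels map to the minimum and are counted in the log.

### Label maps: integer volumes to SEG objects

Each distinct nonzero value becomes one segment, numbered consecutively
from 1 in ascending value order, with segment text `"Label <value>"`
unless a name file overrides it.  At most 30 labels are supported, each
drawn from a fixed 30-color palette (10 hues stepped around the wheel in
three saturation/value rings), converted to DICOM's scaled CIELab encoding
via `grDevices::convertColor`.  The palette is deterministic so the same
structure is the same color at every site, every run.  Non-integer voxel
values are rejected rather than rounded — rounding could merge adjacent
structures.

Frames are binary masks, one per (segment, occupied slice); empty slices
emit no frame, and each frame's plane position is carried explicitly in
the per-frame functional groups.  Frames are compressed with DICOM RLE
(transfer syntax 1.2.840.10008.1.2.5): a 64-byte header of segment
offsets followed by PackBits-style byte streams — literal runs (control
0..127 = length-1) and replicate runs (control 257-length, lengths
2..128), frame padded to even length.  Because this byte-oriented codec
and 1-bit packed segmentation frames are mutually exclusive, frames store
one byte per pixel (BitsAllocated 8).  Runs of at least 2 are emitted as
replicate runs; the reserved control byte 128 is never written and is
skipped on read.  The codec identity `decode(encode(x)) == x` is tested on
random and adversarial byte strings, and the encoder is cross-checked
against an independently written decoder.

A label map must match the voxel grid of one structural input — shape,
spacing and direction cosines within 1e-3 — and the SEG derives from the
first match in input order.  Origins are deliberately *not* compared:
coregistered images may legitimately differ in origin, and coregistration
is never checked (principle 1).  Each frame references the MR instance of
the matching slice as its derivation source.

### Tractograms: tck streamlines to Surface Segmentation

The `.tck` format is a text header (magic line, `key: value` entries, an
`END` line) followed by raw binary coordinate triplets at the offset named
by the header's `file` entry; a NaN triplet closes each streamline and an
Inf triplet closes the stream.  The reader accepts Float32 and Float64 in
either byte order and preserves unknown header keys verbatim for
provenance.  A mismatch between the header `count` and the streamlines
actually present is an error by default (silent truncation being the
dangerous failure mode) and a warning under `--lenient`.  Single-point
streamlines are preserved: the converter has no mandate to filter.

Each tck file becomes one Surface Segmentation object (the SEG-modality
IOD that carries the Surface Mesh Module).  All points are concatenated —
converted to LPS, stored at their native 32-bit precision — into one
surface point list, and every streamline becomes one Line Sequence
primitive whose 1-based indices (`LongPrimitivePointIndexList`) form a
contiguous run; the runs partition the point list in input order, so the
object is exactly invertible back to the tractogram, which
`surface_to_tractogram()` does and the tests verify at float32 precision.
Tract objects always derive from the *first* structural input, and each
carries a recommended display color from the same 30-color palette in
input order; orientation-based coloring seen in viewers is rendering
behaviour, not stored data, so nothing of it is encoded.

### The command line

`importTractography` mirrors the converter's published interface:

```
importTractography --dicom-template T.dcm \
    --nifti T1.nii.gz FLAIR.nii.gz \
    --tract-files cst.tck or.tck \
    --label-files tumour.nii.gz \
    --output-dir dicomdir
```

`--seed`, `--lenient`, `--new-study-uid`, `--label-names` and
`--fixed-clock` are additive extensions.  Output files are laid out as
`<series number>/<modality>.<instance number>.dcm`, and a `manifest.json`
records every input-to-output mapping, all UIDs, geometry-match decisions
and warnings.  On error the partially written DICOM files are removed,
leaving only the failure manifest; exit codes are 0 (success), 2 (usage),
3 (input format) and 4 (geometry).

## UIDs, determinism and the clock

UIDs use the standard UUID-derived numeric root `2.25.` followed by 30
digits from an internal Park–Miller generator, so UID minting never
disturbs the caller's R random stream.  Unseeded runs draw from the wall
clock and process id (practically globally unique); with `--seed`, the
full UID set is a pure function of the seed.  Content dates and times
default to the current clock; `--fixed-clock` pins them, which together
with `--seed` makes reruns byte-identical — the property the pipeline
tests assert.

## The synthetic fixture generators

The package tests itself (and can demo itself) without any clinical data:

* `make_phantom_volume()` — sphere (filled ball, radius `min(shape)/4`
  voxels by default, interior rule `distance^2 <= radius^2` about the grid
  centre `(shape-1)/2`), linear gradient (`i + 2j + 3k`), or seeded
  Gaussian noise.
* `make_label_blobs()` — up to 30 disjoint spheres on a cell lattice,
  with an explicit over-limit mode that builds 31+ labels to exercise the
  error path.
* `make_helical_tracts()` — helices `centre + (r cos t, r sin t, c t)`
  with seed-drawn radius (5–30 mm), pitch, phase and point count (10–60),
  chosen to span the coordinate magnitudes of real tractography.
* `make_minimal_template_dicom()` — the smallest Part-10 file carrying the
  whitelisted attributes; a synthetic stand-in for a session file.

Fixture sizes stay at or below 64 voxels per axis and a few dozen
streamlines so the full suite runs in well under a minute of compute; the
round-trip and geometry properties being exercised are
resolution-independent, so small grids lose no generality.  What the
phantoms deliberately do **not** emulate: brain anatomy, MR noise and bias
fields, partial-volume label boundaries, or the very large streamline
counts of whole-brain tractography.  Passing tests therefore demonstrate
format and geometry correctness, not clinical plausibility of content —
which is the converter's whole remit, since it never interprets image
content.

## Numerical choices and edge cases

* Orthogonality tolerance 1e-4 on unit-axis dot products; geometry match
  tolerance 1e-3 on spacings and cosines; voxel-centre reconstruction
  tolerance 1e-3 mm (observed ~1e-8 mm).
* Decimal-string attributes are written with 10 significant digits within
  DICOM's 16-character limit, keeping position error far below the
  geometry tolerance.
* tck floats are written Float32LE (the format's native precision); the
  read side converts wider encodings to double.
* The tck `count` field, empty label maps, non-finite streamline points,
  label values above 16 bits, and RLE payloads truncated mid-run are all
  hard errors with classed conditions.
* sform is preferred over qform when both are present in a NIfTI header;
  the choice is logged in the manifest-producing layer.

## Known limitations

* The DICOM reader in this package parses only what the writer emits
  (Explicit VR Little Endian, plus RLE-encapsulated frames); implicit-VR
  template files are refused with a clear message.
* Fractional/probabilistic segmentations, triangulated tube meshes around
  streamlines, per-vertex scalars, and TrackVis/VTK formats are out of
  scope, as are DICOM networking and any vendor-private tags.
* One frame set per segment: overlapping structures should arrive as
  separate label files.
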