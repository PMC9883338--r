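# dicomnav

Research neuroimaging pipelines end in NIfTI volumes and MRtrix `.tck`
streamline files; surgical planning and navigation workstations speak
DICOM.  `dicomnav` is an R package that converts a complete, coregistered
neurosurgical workup into a DICOM dataset the navigation suite can import
and treat as native data — 3D tract objects, colored segmentations and
background images, all fused in one coordinate frame — rather than as a
stack of screenshots.

It is written for neuroimaging analysts who prepare surgical workups with
research tools and need to hand the results to clinicians inside the
clinical workflow.

## What it emits

Given a template DICOM file (for patient/institution attributes), one or
more coregistered structural NIfTI images, and optional `.tck` tractogram
and NIfTI label-map inputs, one conversion run produces:

| Input | DICOM object | Details |
|---|---|---|
| structural NIfTI | classic MR Image Storage series | one file per slice, u16 pixels with rescale slope/intercept; geometry from the NIfTI affine via RAS→LPS (voxel-centre agreement ≤ 1e-3 mm) |
| integer label map | Segmentation (SEG) object | one segment per distinct nonzero value (≤ 30), each a distinct palette color; binary frames compressed with DICOM RLE (Annex-G PackBits); derives from the geometry-matched MR series |
| `.tck` tractogram | Surface Segmentation object | each streamline a Line Sequence polyline over a shared float32 LPS point list; derives from the first structural series |

Every object of a run carries the same frame-of-reference UID, which is
what lets the workstation fuse them.  The converter never resamples,
never reorients, and never performs or checks coregistration; sheared
grids, 4D images, >30 labels, non-integer labels and truncated tck files
are hard errors, not guesses.

## Worked example

The package can generate a complete synthetic workup and convert it —
no clinical data required:

```r
library(dicomnav)
wk <- make_demo_workup("workup", seed = 1, shape = c(24L, 24L, 16L))
job <- conversion_job(wk$template, wk$structural, wk$tracts, wk$labels,
                      output_dir = "dicomdir", seed = 1)
m <- run_conversion(job)
```

which logs:

```
[dicomnav] study UID copied from template (converted objects join the original study)
[dicomnav] MR series 1 (16 instances) <- workup/structural1.nii.gz
[dicomnav] tract object from workup/tract1.tck derives from first structural series 2.25.754436111247953095845668608536
[dicomnav] Surface object 2 <- workup/tract1.tck
[dicomnav] tract object from workup/tract2.tck derives from first structural series 2.25.754436111247953095845668608536
[dicomnav] Surface object 3 <- workup/tract2.tck
[dicomnav] label image workup/labels1.nii.gz geometry-matched to structural input 1 (workup/structural1.nii.gz)
[dicomnav] SEG object 4 (3 segments) <- workup/labels1.nii.gz
```

and leaves a ready-to-import directory: 16 MR slice files under `1/`,
two Surface Segmentation tract objects under `2/` and `3/`, a 3-segment
SEG object under `4/`, and a `manifest.json` recording every
input→output mapping and UID.  Reading a fixture back:

```r
read_tck(wk$tracts[1])
#> tractogram: 20 streamlines, 777 points (RAS mm)
```

The same conversion is available from a shell via the bundled script:

```sh
Rscript inst/cli/importTractography \
    --dicom-template workup/template.dcm \
    --nifti workup/structural1.nii.gz \
    --tract-files workup/tract1.tck workup/tract2.tck \
    --label-files workup/labels1.nii.gz \
    --output-dir dicomdir
```

Exit codes: 0 success, 2 usage, 3 input format, 4 geometry.  `--seed` and
`--fixed-clock` make reruns byte-identical; `--lenient`,
`--new-study-uid` and `--label-names` are documented in `?conversion_job`.

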