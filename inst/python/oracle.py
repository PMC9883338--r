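#!/usr/bin/env python
"""Independent-reader oracle for the test suite.

Uses pydicom and nibabel (not the R implementation under test) to parse
emitted DICOM and tck files, run conformance checks, decode pixel data and
recompose label volumes.  Every subcommand prints a single JSON object.
"""

import base64
import json
import sys

import numpy as np
import pydicom

MR_STORAGE = "1.2.840.10008.5.1.4.1.1.4"
SEG_STORAGE = "1.2.840.10008.5.1.4.1.1.66.4"
SURF_STORAGE = "1.2.840.10008.5.1.4.1.1.66.5"

REQUIRED = {
    MR_STORAGE: [
        "SOPClassUID", "SOPInstanceUID", "StudyInstanceUID",
        "SeriesInstanceUID", "FrameOfReferenceUID", "Modality", "ImageType",
        "Rows", "Columns", "BitsAllocated", "BitsStored", "HighBit",
        "PixelRepresentation", "SamplesPerPixel", "PhotometricInterpretation",
        "PixelSpacing", "ImagePositionPatient", "ImageOrientationPatient",
        "ScanningSequence", "SequenceVariant", "PixelData",
        "PatientName", "PatientID",
    ],
    SEG_STORAGE: [
        "SOPClassUID", "SOPInstanceUID", "StudyInstanceUID",
        "SeriesInstanceUID", "FrameOfReferenceUID", "Modality",
        "SegmentationType", "SegmentSequence", "NumberOfFrames",
        "Rows", "Columns", "SharedFunctionalGroupsSequence",
        "PerFrameFunctionalGroupsSequence", "ContentLabel", "PixelData",
        "PatientName", "PatientID",
    ],
    SURF_STORAGE: [
        "SOPClassUID", "SOPInstanceUID", "StudyInstanceUID",
        "SeriesInstanceUID", "FrameOfReferenceUID", "Modality",
        "SegmentSequence", "NumberOfSurfaces", "SurfaceSequence",
        "ContentLabel", "PatientName", "PatientID",
    ],
}


def emit(obj):
    json.dump(obj, sys.stdout)
    sys.stdout.write("\n")


def validate(path):
    errors = []
    try:
        ds = pydicom.dcmread(path)
    except Exception as exc:  # noqa: BLE001
        emit({"ok": False, "errors": [f"unreadable: {exc}"]})
        return
    sop = str(ds.SOPClassUID) if "SOPClassUID" in ds else None
    required = REQUIRED.get(sop, ["SOPClassUID", "SOPInstanceUID"])
    for kw in required:
        if kw not in ds:
            errors.append(f"missing {kw}")
    if sop == MR_STORAGE and "Modality" in ds and ds.Modality != "MR":
        errors.append("MR storage with modality " + str(ds.Modality))
    if sop in (SEG_STORAGE, SURF_STORAGE) and "Modality" in ds \
            and ds.Modality != "SEG":
        errors.append("segmentation object with modality " + str(ds.Modality))
    if sop == SEG_STORAGE:
        try:
            arr = ds.pixel_array
            nf = int(ds.NumberOfFrames)
            if arr.shape[0] != nf and nf != 1:
                errors.append(f"decoded {arr.shape[0]} frames, header says {nf}")
            if len(ds.PerFrameFunctionalGroupsSequence) != nf:
                errors.append("per-frame group count != NumberOfFrames")
        except Exception as exc:  # noqa: BLE001
            errors.append(f"pixel data undecodable: {exc}")
        if ds.file_meta.TransferSyntaxUID != "1.2.840.10008.1.2.5":
            errors.append("SEG not in RLE Lossless transfer syntax")
        for i, seg in enumerate(ds.SegmentSequence, start=1):
            if int(seg.SegmentNumber) != i:
                errors.append("segment numbers not consecutive from 1")
            for kw in ("SegmentLabel", "SegmentAlgorithmType",
                       "RecommendedDisplayCIELabValue"):
                if kw not in seg:
                    errors.append(f"segment {i} missing {kw}")
    if sop == SURF_STORAGE:
        surf = ds.SurfaceSequence[0]
        for kw in ("SurfacePointsSequence", "SurfaceMeshPrimitivesSequence",
                   "SurfaceNumber"):
            if kw not in surf:
                errors.append(f"surface missing {kw}")
    emit({"ok": not errors, "sop_class": sop, "errors": errors,
          "transfer_syntax": str(ds.file_meta.TransferSyntaxUID),
          "frame_of_reference": str(getattr(ds, "FrameOfReferenceUID", "")),
          "series_uid": str(getattr(ds, "SeriesInstanceUID", "")),
          "study_uid": str(getattr(ds, "StudyInstanceUID", "")),
          "modality": str(getattr(ds, "Modality", ""))})


def mr_info(path, with_pixels):
    ds = pydicom.dcmread(path)
    arr = ds.pixel_array.astype(np.float64)
    decoded = arr * float(ds.RescaleSlope) + float(ds.RescaleIntercept)
    out = {
        "rows": int(ds.Rows), "columns": int(ds.Columns),
        "ipp": [float(x) for x in ds.ImagePositionPatient],
        "iop": [float(x) for x in ds.ImageOrientationPatient],
        "pixel_spacing": [float(x) for x in ds.PixelSpacing],
        "slice_thickness": float(ds.SliceThickness),
        "slope": float(ds.RescaleSlope),
        "intercept": float(ds.RescaleIntercept),
        "instance_number": int(ds.InstanceNumber),
        "series_uid": str(ds.SeriesInstanceUID),
        "frame_of_reference": str(ds.FrameOfReferenceUID),
        "min": float(decoded.min()), "max": float(decoded.max()),
    }
    if with_pixels:
        # row-major: rows outer, columns inner (DICOM transmission order)
        out["decoded"] = [float(v) for v in decoded.reshape(-1)]
    emit(out)


def seg_recompose(path):
    """Rebuild (value, column i, row j, slice k) voxels from a SEG file."""
    ds = pydicom.dcmread(path)
    frames = ds.pixel_array
    nf = int(ds.NumberOfFrames)
    if nf == 1:
        frames = frames.reshape((1,) + frames.shape[-2:])
    labels = {}
    for seg in ds.SegmentSequence:
        txt = str(getattr(seg, "SegmentLabel", ""))
        try:
            value = int(txt.replace("Label", "").strip())
        except ValueError:
            value = int(seg.SegmentNumber)
        labels[int(seg.SegmentNumber)] = value
    pfg = ds.PerFrameFunctionalGroupsSequence
    positions = []
    for item in pfg:
        positions.append([float(x)
                          for x in item.PlanePositionSequence[0].ImagePositionPatient])
    voxels = []
    for f in range(nf):
        seg_num = int(pfg[f].SegmentIdentificationSequence[0]
                      .ReferencedSegmentNumber)
        value = labels[seg_num]
        rows, cols = np.nonzero(frames[f])
        for r, c in zip(rows.tolist(), cols.tolist()):
            voxels.append([value, c, r, f])
    refs = []
    for item in pfg:
        try:
            refs.append(str(item.DerivationImageSequence[0]
                            .SourceImageSequence[0].ReferencedSOPInstanceUID))
        except Exception:  # noqa: BLE001
            refs.append("")
    emit({"n_frames": nf, "rows": int(ds.Rows), "columns": int(ds.Columns),
          "n_segments": len(ds.SegmentSequence),
          "segment_values": [labels[i + 1] for i in range(len(labels))],
          "frame_positions": positions,
          "frame_source_instances": refs,
          "voxels": voxels})


def read_tck(path):
    import nibabel as nib
    tck = nib.streamlines.load(path)
    sl = tck.streamlines
    emit({"count": len(sl),
          "lengths": [int(len(s)) for s in sl],
          "points": [[float(v) for v in p] for s in sl for p in s]})


def surface_info(path):
    ds = pydicom.dcmread(path)
    surf = ds.SurfaceSequence[0]
    pts_item = surf.SurfacePointsSequence[0]
    n = int(pts_item.NumberOfSurfacePoints)
    coords = np.frombuffer(pts_item.PointCoordinatesData, dtype="<f4")
    lines = surf.SurfaceMeshPrimitivesSequence[0].LineSequence
    runs = []
    for item in lines:
        idx = np.frombuffer(item.LongPrimitivePointIndexList, dtype="<u4")
        runs.append([int(v) for v in idx])
    emit({"n_points": n,
          "points": [float(v) for v in coords[:3 * n]],
          "runs": runs,
          "series_uid": str(ds.SeriesInstanceUID),
          "frame_of_reference": str(ds.FrameOfReferenceUID),
          "referenced_series": [str(item.SeriesInstanceUID)
                                for item in ds.ReferencedSeriesSequence]})


def packbits_decode_file(path, expected):
    """Independently written Annex-G decoder (no pydicom RLE code)."""
    with open(path, "rb") as fh:
        frame = fh.read()
    hdr = np.frombuffer(frame[:64], dtype="<u4")
    n_seg = int(hdr[0])
    offsets = [int(v) for v in hdr[1:1 + n_seg]] + [len(frame)]
    out = bytearray()
    for s in range(n_seg):
        seg = frame[offsets[s]:offsets[s + 1]]
        i = 0
        dec = bytearray()
        while i < len(seg) and len(dec) < expected:
            ctrl = seg[i]
            i += 1
            if ctrl <= 127:
                dec += seg[i:i + ctrl + 1]
                i += ctrl + 1
            elif ctrl >= 129:
                dec += bytes([seg[i]]) * (257 - ctrl)
                i += 1
        out += dec[:expected]
    emit({"decoded_b64": base64.b64encode(bytes(out)).decode("ascii"),
          "n_segments": n_seg})


def template_info(path):
    ds = pydicom.dcmread(path)
    out = {}
    for kw in ("PatientID", "PatientName", "PatientSex", "StudyDate",
               "StudyDescription", "InstitutionName", "StudyInstanceUID",
               "AccessionNumber"):
        if kw in ds:
            out[kw] = str(ds[kw].value)
    emit(out)


def main(argv):
    cmd = argv[1]
    if cmd == "validate":
        validate(argv[2])
    elif cmd == "mr-info":
        mr_info(argv[2], "--pixels" in argv)
    elif cmd == "seg-recompose":
        seg_recompose(argv[2])
    elif cmd == "read-tck":
        read_tck(argv[2])
    elif cmd == "surface-info":
        surface_info(argv[2])
    elif cmd == "packbits-decode":
        packbits_decode_file(argv[2], int(argv[3]))
    elif cmd == "template-info":
        template_info(argv[2])
    else:
        raise SystemExit(f"unknown subcommand {cmd}")


if __name__ == "__main__":
    main(sys.argv)
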