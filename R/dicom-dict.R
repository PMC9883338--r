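# Minimal DICOM data dictionary: only the attributes this package emits or
# reads.  Tags are (group, element) integers; VRs follow PS3.6.

.dcm_dict_raw <- list(
  # file meta (group 0002)
  FileMetaInformationGroupLength = list(0x0002L, 0x0000L, "UL"),
  FileMetaInformationVersion     = list(0x0002L, 0x0001L, "OB"),
  MediaStorageSOPClassUID        = list(0x0002L, 0x0002L, "UI"),
  MediaStorageSOPInstanceUID     = list(0x0002L, 0x0003L, "UI"),
  TransferSyntaxUID              = list(0x0002L, 0x0010L, "UI"),
  ImplementationClassUID         = list(0x0002L, 0x0012L, "UI"),
  ImplementationVersionName      = list(0x0002L, 0x0013L, "SH"),
  # group 0008
  SpecificCharacterSet        = list(0x0008L, 0x0005L, "CS"),
  ImageType                   = list(0x0008L, 0x0008L, "CS"),
  SOPClassUID                 = list(0x0008L, 0x0016L, "UI"),
  SOPInstanceUID              = list(0x0008L, 0x0018L, "UI"),
  StudyDate                   = list(0x0008L, 0x0020L, "DA"),
  SeriesDate                  = list(0x0008L, 0x0021L, "DA"),
  ContentDate                 = list(0x0008L, 0x0023L, "DA"),
  StudyTime                   = list(0x0008L, 0x0030L, "TM"),
  SeriesTime                  = list(0x0008L, 0x0031L, "TM"),
  ContentTime                 = list(0x0008L, 0x0033L, "TM"),
  AccessionNumber             = list(0x0008L, 0x0050L, "SH"),
  Modality                    = list(0x0008L, 0x0060L, "CS"),
  Manufacturer                = list(0x0008L, 0x0070L, "LO"),
  InstitutionName             = list(0x0008L, 0x0080L, "LO"),
  ReferringPhysicianName      = list(0x0008L, 0x0090L, "PN"),
  CodeValue                   = list(0x0008L, 0x0100L, "SH"),
  CodingSchemeDesignator      = list(0x0008L, 0x0102L, "SH"),
  CodeMeaning                 = list(0x0008L, 0x0104L, "LO"),
  StudyDescription            = list(0x0008L, 0x1030L, "LO"),
  SeriesDescription           = list(0x0008L, 0x103EL, "LO"),
  ManufacturerModelName       = list(0x0008L, 0x1090L, "LO"),
  ReferencedSeriesSequence    = list(0x0008L, 0x1115L, "SQ"),
  ReferencedImageSequence     = list(0x0008L, 0x1140L, "SQ"),
  ReferencedInstanceSequence  = list(0x0008L, 0x114AL, "SQ"),
  ReferencedSOPClassUID       = list(0x0008L, 0x1150L, "UI"),
  ReferencedSOPInstanceUID    = list(0x0008L, 0x1155L, "UI"),
  DerivationDescription       = list(0x0008L, 0x2111L, "ST"),
  SourceImageSequence         = list(0x0008L, 0x2112L, "SQ"),
  DerivationImageSequence     = list(0x0008L, 0x9124L, "SQ"),
  DerivationCodeSequence      = list(0x0008L, 0x9215L, "SQ"),
  # group 0010
  PatientName      = list(0x0010L, 0x0010L, "PN"),
  PatientID        = list(0x0010L, 0x0020L, "LO"),
  PatientBirthDate = list(0x0010L, 0x0030L, "DA"),
  PatientSex       = list(0x0010L, 0x0040L, "CS"),
  # group 0018
  ScanningSequence     = list(0x0018L, 0x0020L, "CS"),
  SequenceVariant      = list(0x0018L, 0x0021L, "CS"),
  ScanOptions          = list(0x0018L, 0x0022L, "CS"),
  MRAcquisitionType    = list(0x0018L, 0x0023L, "CS"),
  SliceThickness       = list(0x0018L, 0x0050L, "DS"),
  RepetitionTime       = list(0x0018L, 0x0080L, "DS"),
  EchoTime             = list(0x0018L, 0x0081L, "DS"),
  SpacingBetweenSlices = list(0x0018L, 0x0088L, "DS"),
  EchoTrainLength      = list(0x0018L, 0x0091L, "IS"),
  SoftwareVersions     = list(0x0018L, 0x1020L, "LO"),
  # group 0020
  StudyInstanceUID              = list(0x0020L, 0x000DL, "UI"),
  SeriesInstanceUID             = list(0x0020L, 0x000EL, "UI"),
  StudyID                       = list(0x0020L, 0x0010L, "SH"),
  SeriesNumber                  = list(0x0020L, 0x0011L, "IS"),
  InstanceNumber                = list(0x0020L, 0x0013L, "IS"),
  ImagePositionPatient          = list(0x0020L, 0x0032L, "DS"),
  ImageOrientationPatient       = list(0x0020L, 0x0037L, "DS"),
  FrameOfReferenceUID           = list(0x0020L, 0x0052L, "UI"),
  PositionReferenceIndicator    = list(0x0020L, 0x1040L, "LO"),
  FrameContentSequence          = list(0x0020L, 0x9111L, "SQ"),
  PlanePositionSequence         = list(0x0020L, 0x9113L, "SQ"),
  PlaneOrientationSequence      = list(0x0020L, 0x9116L, "SQ"),
  DimensionIndexValues          = list(0x0020L, 0x9157L, "UL"),
  DimensionOrganizationUID      = list(0x0020L, 0x9164L, "UI"),
  DimensionIndexPointer         = list(0x0020L, 0x9165L, "AT"),
  FunctionalGroupPointer        = list(0x0020L, 0x9167L, "AT"),
  DimensionOrganizationSequence = list(0x0020L, 0x9221L, "SQ"),
  DimensionIndexSequence        = list(0x0020L, 0x9222L, "SQ"),
  # group 0028
  SamplesPerPixel           = list(0x0028L, 0x0002L, "US"),
  PhotometricInterpretation = list(0x0028L, 0x0004L, "CS"),
  NumberOfFrames            = list(0x0028L, 0x0008L, "IS"),
  Rows                      = list(0x0028L, 0x0010L, "US"),
  Columns                   = list(0x0028L, 0x0011L, "US"),
  PixelSpacing              = list(0x0028L, 0x0030L, "DS"),
  BitsAllocated             = list(0x0028L, 0x0100L, "US"),
  BitsStored                = list(0x0028L, 0x0101L, "US"),
  HighBit                   = list(0x0028L, 0x0102L, "US"),
  PixelRepresentation       = list(0x0028L, 0x0103L, "US"),
  RescaleIntercept          = list(0x0028L, 0x1052L, "DS"),
  RescaleSlope              = list(0x0028L, 0x1053L, "DS"),
  RescaleType               = list(0x0028L, 0x1054L, "LO"),
  LossyImageCompression     = list(0x0028L, 0x2110L, "CS"),
  PixelMeasuresSequence     = list(0x0028L, 0x9110L, "SQ"),
  # group 0040
  PurposeOfReferenceCodeSequence = list(0x0040L, 0xA170L, "SQ"),
  # group 0062 (segmentation)
  SegmentationType                       = list(0x0062L, 0x0001L, "CS"),
  SegmentSequence                        = list(0x0062L, 0x0002L, "SQ"),
  SegmentedPropertyCategoryCodeSequence  = list(0x0062L, 0x0003L, "SQ"),
  SegmentNumber                          = list(0x0062L, 0x0004L, "US"),
  SegmentLabel                           = list(0x0062L, 0x0005L, "LO"),
  SegmentAlgorithmType                   = list(0x0062L, 0x0008L, "CS"),
  SegmentAlgorithmName                   = list(0x0062L, 0x0009L, "LO"),
  SegmentIdentificationSequence          = list(0x0062L, 0x000AL, "SQ"),
  ReferencedSegmentNumber                = list(0x0062L, 0x000BL, "US"),
  RecommendedDisplayCIELabValue          = list(0x0062L, 0x000DL, "US"),
  SegmentedPropertyTypeCodeSequence      = list(0x0062L, 0x000FL, "SQ"),
  # group 0066 (surface mesh)
  NumberOfSurfaces                 = list(0x0066L, 0x0001L, "UL"),
  SurfaceSequence                  = list(0x0066L, 0x0002L, "SQ"),
  SurfaceNumber                    = list(0x0066L, 0x0003L, "UL"),
  SurfaceComments                  = list(0x0066L, 0x0004L, "LT"),
  SurfaceProcessing                = list(0x0066L, 0x0009L, "CS"),
  SurfaceProcessingRatio           = list(0x0066L, 0x000AL, "FL"),
  RecommendedPresentationOpacity   = list(0x0066L, 0x000CL, "FL"),
  RecommendedPresentationType      = list(0x0066L, 0x000DL, "CS"),
  FiniteVolume                     = list(0x0066L, 0x000EL, "CS"),
  Manifold                         = list(0x0066L, 0x0010L, "CS"),
  SurfacePointsSequence            = list(0x0066L, 0x0011L, "SQ"),
  SurfacePointsNormalsSequence     = list(0x0066L, 0x0012L, "SQ"),
  SurfaceMeshPrimitivesSequence    = list(0x0066L, 0x0013L, "SQ"),
  NumberOfSurfacePoints            = list(0x0066L, 0x0015L, "UL"),
  PointCoordinatesData             = list(0x0066L, 0x0016L, "OF"),
  TriangleStripSequence            = list(0x0066L, 0x0026L, "SQ"),
  TriangleFanSequence              = list(0x0066L, 0x0027L, "SQ"),
  LineSequence                     = list(0x0066L, 0x0028L, "SQ"),
  SurfaceCount                     = list(0x0066L, 0x002AL, "UL"),
  ReferencedSurfaceSequence        = list(0x0066L, 0x002BL, "SQ"),
  ReferencedSurfaceNumber          = list(0x0066L, 0x002CL, "UL"),
  SegmentSurfaceGenerationAlgorithmIdentificationSequence =
    list(0x0066L, 0x002DL, "SQ"),
  SegmentSurfaceSourceInstanceSequence = list(0x0066L, 0x002EL, "SQ"),
  AlgorithmFamilyCodeSequence      = list(0x0066L, 0x002FL, "SQ"),
  AlgorithmVersion                 = list(0x0066L, 0x0031L, "LO"),
  FacetSequence                    = list(0x0066L, 0x0034L, "SQ"),
  AlgorithmName                    = list(0x0066L, 0x0036L, "LO"),
  LongPrimitivePointIndexList      = list(0x0066L, 0x0040L, "OL"),
  # group 5200 (multi-frame functional groups)
  SharedFunctionalGroupsSequence   = list(0x5200L, 0x9229L, "SQ"),
  PerFrameFunctionalGroupsSequence = list(0x5200L, 0x9230L, "SQ"),
  # group 0070
  ContentLabel       = list(0x0070L, 0x0080L, "CS"),
  ContentDescription = list(0x0070L, 0x0081L, "LO"),
  ContentCreatorName = list(0x0070L, 0x0084L, "PN"),
  # pixel data
  PixelData = list(0x7FE0L, 0x0010L, "OW")
)

.dcm_dict <- local({
  d <- lapply(.dcm_dict_raw, function(x) {
    list(group = x[[1]], element = x[[2]], vr = x[[3]])
  })
  d
})

# reverse lookup: "GGGGEEEE" -> keyword
.dcm_keys <- local({
  k <- vapply(.dcm_dict, function(x) sprintf("%04X%04X", x$group, x$element), "")
  stats::setNames(names(.dcm_dict), k)
})

# DICOM UIDs used by the writers
DCM_UID <- list(
  explicit_vr_le      = "1.2.840.10008.1.2.1",
  implicit_vr_le      = "1.2.840.10008.1.2",
  rle_lossless        = "1.2.840.10008.1.2.5",
  mr_image_storage    = "1.2.840.10008.5.1.4.1.1.4",
  segmentation_storage = "1.2.840.10008.5.1.4.1.1.66.4",
  surface_segmentation_storage = "1.2.840.10008.5.1.4.1.1.66.5",
  secondary_capture   = "1.2.840.10008.5.1.4.1.1.7"
)

dcm_tag_lookup <- function(keyword) {
  entry <- .dcm_dict[[keyword]]
  if (is.null(entry)) stop("unknown DICOM keyword: ", keyword, call. = FALSE)
  entry
}

dcm_tag_key <- function(group, element) sprintf("%04X%04X", group, element)
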