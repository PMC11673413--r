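# PASCAL VOC2007 annotation I/O. The XML dialect stores 1-based inclusive
# integer corners; internally boxes are continuous, 0-based and half-open, so
# min corners lose 1 on read and regain it on write, while max corners carry
# over unchanged (an inclusive max corner of pixel column j is the half-open
# bound j in 0-based coordinates). Two dialect extensions are used: a
# <plane> element under <annotation> and a <lesion_id> element per <object>,
# grouping the slices of one lesion across planes.

VOC_CLASSES <- c("benign", "malignant")

#' Construct a VOC record
#'
#' @param image_path path of the image the annotations refer to.
#' @param image_size integer `c(width, height)` in pixels.
#' @param annotations tibble with columns `x_min`, `y_min`, `x_max`, `y_max`,
#'   `label` (`"benign"` or `"malignant"`), `lesion_id`, `plane`.
#' @param plane slice orientation, `"axial"` or `"sagittal"`.
#' @return An object of class `voc_record`.
#' @export
voc_record <- function(image_path, image_size, annotations = NULL,
                       plane = c("axial", "sagittal")) {
  plane <- match.arg(plane)
  if (is.null(annotations))
    annotations <- tibble::tibble(x_min = numeric(), y_min = numeric(),
                                  x_max = numeric(), y_max = numeric(),
                                  label = character(), lesion_id = character(),
                                  plane = character())
  rec <- structure(list(image_path = image_path,
                        image_size = as.integer(image_size),
                        annotations = tibble::as_tibble(annotations),
                        plane = plane),
                   class = "voc_record")
  validate_voc_record(rec)
}

validate_voc_record <- function(rec) {
  ann <- rec$annotations
  if (nrow(ann)) {
    bad <- setdiff(unique(ann$label), VOC_CLASSES)
    if (length(bad))
      stop("unknown class name(s) ", paste(bad, collapse = ", "),
           "; allowed: ", paste(VOC_CLASSES, collapse = ", "))
    if (any(!nzchar(ann$lesion_id))) stop("lesion_id must be non-empty")
    validate_boxes(ann)
    rec$annotations <- clip_boxes(ann, rec$image_size[1], rec$image_size[2])
  }
  rec
}

#' Read a VOC2007 annotation file
#'
#' Class names are matched case-insensitively against `benign`/`malignant`;
#' `difficult` and `truncated` flags are tolerated and ignored. Corner
#' conversion: VOC 1-based inclusive integers become continuous 0-based
#' half-open coordinates (min corners minus 1, max corners unchanged).
#'
#' @param path an annotation XML file.
#' @return A [voc_record()].
#' @export
read_voc_annotation <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("failed to parse VOC XML '", path,
                                           "': ", conditionMessage(e)))
  sz <- xml2::xml_find_first(doc, "./size")
  width <- as.integer(xml2::xml_text(xml2::xml_find_first(sz, "./width")))
  height <- as.integer(xml2::xml_text(xml2::xml_find_first(sz, "./height")))
  fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  plane_node <- xml2::xml_find_first(doc, "./plane")
  plane <- if (inherits(plane_node, "xml_missing")) "axial" else xml2::xml_text(plane_node)
  objs <- xml2::xml_find_all(doc, "./object")
  txt <- function(node, xp) xml2::xml_text(xml2::xml_find_first(node, xp))
  ann <- purrr::map_dfr(objs, function(o) {
    label <- tolower(trimws(txt(o, "./name")))
    lid_node <- xml2::xml_find_first(o, "./lesion_id")
    lid <- if (inherits(lid_node, "xml_missing")) label else xml2::xml_text(lid_node)
    tibble::tibble(
      x_min = as.numeric(txt(o, "./bndbox/xmin")) - 1,
      y_min = as.numeric(txt(o, "./bndbox/ymin")) - 1,
      x_max = as.numeric(txt(o, "./bndbox/xmax")),
      y_max = as.numeric(txt(o, "./bndbox/ymax")),
      label = label, lesion_id = lid, plane = plane)
  })
  if (!nrow(ann))
    ann <- NULL
  voc_record(image_path = fname, image_size = c(width, height),
             annotations = ann, plane = plane)
}

#' Write a VOC2007 annotation file
#'
#' Inverse of [read_voc_annotation()]; rewriting a freshly read record
#' reproduces the annotation up to integer rounding of the corners.
#'
#' @param record a [voc_record()].
#' @param path output XML path.
#' @return `path`, invisibly.
#' @export
write_voc_annotation <- function(record, path) {
  record <- validate_voc_record(record)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "JPEGImages")
  xml2::xml_add_child(doc, "filename", basename(record$image_path))
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "width", as.character(record$image_size[1]))
  xml2::xml_add_child(sz, "height", as.character(record$image_size[2]))
  xml2::xml_add_child(sz, "depth", "1")
  xml2::xml_add_child(doc, "plane", record$plane)
  ann <- record$annotations
  if (nrow(ann)) {
    for (i in seq_len(nrow(ann))) {
      o <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(o, "name", ann$label[i])
      xml2::xml_add_child(o, "lesion_id", ann$lesion_id[i])
      xml2::xml_add_child(o, "difficult", "0")
      bb <- xml2::xml_add_child(o, "bndbox")
      xml2::xml_add_child(bb, "xmin", as.character(round(ann$x_min[i]) + 1L))
      xml2::xml_add_child(bb, "ymin", as.character(round(ann$y_min[i]) + 1L))
      xml2::xml_add_child(bb, "xmax", as.character(round(ann$x_max[i])))
      xml2::xml_add_child(bb, "ymax", as.character(round(ann$y_max[i])))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' List a VOC2007 dataset directory
#'
#' Expects the layout `JPEGImages/`, `Annotations/`,
#' `ImageSets/Main/{train,val,test}.txt`.
#'
#' @param dir dataset root.
#' @param split one of `"train"`, `"val"`, `"test"`, or `NULL` for all
#'   annotated images.
#' @return A tibble with `image_id`, `image_path`, `annotation_path`.
#' @export
voc_dataset <- function(dir, split = NULL) {
  if (!is.null(split)) {
    f <- file.path(dir, "ImageSets", "Main", paste0(split, ".txt"))
    if (!file.exists(f)) stop("split file not found: ", f)
    ids <- readLines(f)
    ids <- ids[nzchar(ids)]
  } else {
    ids <- sub("\\.xml$", "", list.files(file.path(dir, "Annotations"),
                                         pattern = "\\.xml$"))
  }
  tibble::tibble(
    image_id = ids,
    image_path = file.path(dir, "JPEGImages", paste0(ids, ".png")),
    annotation_path = file.path(dir, "Annotations", paste0(ids, ".xml")))
}
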