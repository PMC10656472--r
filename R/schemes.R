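#' Label schemes for multiclass TBI lesion segmentations
#'
#' A label scheme names the integer codes used in a lesion label volume.
#' Two schemes are in routine use for TBI CT segmentation: a 4-class scheme
#' distinguishing intraparenchymal hematoma (IPH), extra-axial hematoma (EAH),
#' perilesional oedema (Od) and intraventricular hemorrhage (IVH), and a
#' refined 7-class scheme that splits EAH into subdural (SDH), epidural (EDH)
#' and subarachnoid (SAH) hemorrhage and separates petechiae (Pe) from IPH.
#' Code 0 is reserved for background in every scheme.
#'
#' `scheme_seven()` carries a merge map onto `scheme_four()` (SDH, EDH, SAH to
#' EAH; Pe to IPH; identity on IPH, Od, IVH), and every scheme can be merged
#' onto `scheme_all()`, the single-class "All" scheme representing lesional
#' tissue of any type.
#'
#' @param name Scheme identifier.
#' @param codes Integer vector of positive, unique class codes.
#' @param labels Character vector of lesion names, parallel to `codes`.
#' @param merge_to Named list: target scheme name -> named integer vector
#'   mapping this scheme's codes (names) to the target's codes (values).
#' @return A `tbq_scheme` object.
#' @examples
#' scheme_seven()
#' merge_map(scheme_seven(), scheme_four())
#' @export
label_scheme <- function(name, codes, labels, merge_to = list()) {
  codes <- as.integer(codes)
  stopifnot(length(codes) == length(labels), all(codes > 0L), !anyDuplicated(codes))
  structure(
    list(name = name, codes = codes, labels = as.character(labels), merge_to = merge_to),
    class = "tbq_scheme"
  )
}

#' @rdname label_scheme
#' @export
scheme_four <- function() {
  label_scheme("four", 1:4, c("IPH", "EAH", "Od", "IVH"),
    merge_to = list(all = c(`1` = 1L, `2` = 1L, `3` = 1L, `4` = 1L))
  )
}

#' @rdname label_scheme
#' @export
scheme_seven <- function() {
  label_scheme("seven", 1:7, c("IPH", "SDH", "EDH", "SAH", "Pe", "Od", "IVH"),
    merge_to = list(
      # SDH/EDH/SAH -> EAH, Pe -> IPH, identity on IPH/Od/IVH
      four = c(`1` = 1L, `2` = 2L, `3` = 2L, `4` = 2L, `5` = 1L, `6` = 3L, `7` = 4L),
      all = c(`1` = 1L, `2` = 1L, `3` = 1L, `4` = 1L, `5` = 1L, `6` = 1L, `7` = 1L)
    )
  )
}

#' @rdname label_scheme
#' @export
scheme_all <- function() {
  label_scheme("all", 1L, "All")
}

#' Look up a scheme by name
#' @param name One of `"four"`, `"seven"`, `"all"`.
#' @return A `tbq_scheme`.
#' @export
get_scheme <- function(name) {
  switch(name,
    four = scheme_four(),
    seven = scheme_seven(),
    all = scheme_all(),
    stop("unknown label scheme: ", name)
  )
}

#' Merge map between two schemes
#'
#' @param from,to `tbq_scheme` objects.
#' @return Named integer vector sending each code of `from` to a code of `to`.
#'   Errors when no map is defined.
#' @export
merge_map <- function(from, to) {
  if (identical(to$name, "all")) {
    m <- rep(1L, length(from$codes))
    names(m) <- from$codes
    return(m)
  }
  m <- from$merge_to[[to$name]]
  if (is.null(m)) {
    stop("no merge map defined from scheme '", from$name, "' to '", to$name, "'")
  }
  m
}

#' @export
print.tbq_scheme <- function(x, ...) {
  cat("<label scheme '", x$name, "'> ", sep = "")
  cat(paste0(x$codes, ":", x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Names of the 11 atlas regions
#'
#' Region order is fixed; codes 1-11 in the atlas grid follow this order, with
#' 0 meaning outside the head.
#' @return Character vector of length 11.
#' @export
atlas_region_names <- function() {
  c(
    "Frontal Lobe", "Parietal Lobe", "Occipital Lobe", "Temporal Lobe",
    "Caudate", "Cerebellum", "Insula", "Putamen", "Thalamus",
    "Rest-of-brain", "Extra-cerebral space"
  )
}
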