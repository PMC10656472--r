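#' The daily TIL item table
#'
#' The therapeutic intensity level (TIL) summary score adds point weights over
#' categories of ICP-directed therapy (sedation, CSF drainage, hyperosmolar
#' therapy, surgery, ...); the daily sum is an integer between 0 and 38. The
#' item table ships as a versioned YAML file so alternative weightings can be
#' swapped in; the 0-38 bound is enforced at load time.
#'
#' @param path YAML file; defaults to the packaged table.
#' @return A `tbq_til_table`: tibble with columns item, level, points, label.
#' @examples
#' tab <- til_item_table()
#' sum(tapply(tab$points, tab$item, max)) # 38
#' @export
til_item_table <- function(path = system.file("extdata", "til_items.yaml",
                                              package = "tbiquant")) {
  raw <- yaml::read_yaml(path)
  rows <- purrr::map_dfr(raw$items, function(it) {
    tibble::tibble(
      item = it$name,
      level = vapply(it$levels, function(l) as.integer(l$level), integer(1)),
      points = vapply(it$levels, function(l) as.integer(l$points), integer(1)),
      label = vapply(it$levels, function(l) as.character(l$label), character(1))
    )
  })
  if (any(rows$points < 0L)) stop("TIL item points must be >= 0")
  mx <- sum(tapply(rows$points, rows$item, max))
  if (mx != 38L) {
    stop("invalid TIL item table: maximum achievable daily sum is ", mx,
         ", must be 38")
  }
  class(rows) <- c("tbq_til_table", class(rows))
  rows
}

#' Daily TILsum from chosen therapy levels
#'
#' @param item_levels Named integer vector or list, item name -> chosen level.
#'   Items omitted default to level 0.
#' @param table A [til_item_table()].
#' @return Integer daily TILsum in \[0, 38\].
#' @examples
#' til_daily(c(sedation = 2, surgery = 1))
#' @export
til_daily <- function(item_levels, table = til_item_table()) {
  item_levels <- unlist(item_levels)
  items <- unique(table$item)
  unknown <- setdiff(names(item_levels), items)
  if (length(unknown)) stop("unknown TIL item(s): ", paste(unknown, collapse = ", "))
  total <- 0L
  for (it in names(item_levels)) {
    sub <- table[table$item == it, ]
    j <- match(as.integer(item_levels[[it]]), sub$level)
    if (is.na(j)) {
      stop("level ", item_levels[[it]], " not allowed for TIL item '", it, "'")
    }
    total <- total + sub$points[j]
  }
  total
}

#' TILsum-based outcome label
#'
#' A day is one of extreme management when its TILsum reaches 11 or more; a
#' patient is `TILsum_High` when any of the first `window_days` daily values
#' (default the first 8 ICU days) reaches the threshold, `TILsum_Low`
#' otherwise. Shorter series use all available days.
#'
#' @param daily Integer vector of daily TILsum values, each in \[0, 38\].
#' @param window_days Days considered, default 8.
#' @param threshold Extreme-management threshold, default 11 (inclusive).
#' @return `"TILsum_High"` or `"TILsum_Low"`.
#' @examples
#' til_outcome(c(0, 11, 0, 0, 0, 0, 0, 0)) # High
#' til_outcome(c(3, 5, 10, 7)) # Low
#' @export
til_outcome <- function(daily, window_days = 8L, threshold = 11L) {
  daily <- as.numeric(daily)
  if (!length(daily)) stop("daily TILsum series must have length >= 1")
  if (any(!is.finite(daily)) || any(daily < 0) || any(daily > 38)) {
    stop("daily TILsum values must lie in [0, 38]")
  }
  w <- daily[seq_len(min(window_days, length(daily)))]
  if (max(w) >= threshold) "TILsum_High" else "TILsum_Low"
}

#' Structured CT findings
#'
#' The inputs of the Marshall and Rotterdam CT severity scores.
#'
#' @param cistern_status One of `"normal"`, `"compressed"`, `"absent"`.
#' @param midline_shift_mm Midline shift in mm, >= 0.
#' @param mass_lesion_volume_cm3 Largest high/mixed-density lesion volume, cm^3.
#' @param evacuated Was a mass lesion surgically evacuated?
#' @param epidural_mass_present Epidural mass lesion present?
#' @param ivh_or_tsah_present Intraventricular or traumatic subarachnoid blood?
#' @return A `tbq_ct_findings` list.
#' @export
ct_findings <- function(cistern_status = "normal", midline_shift_mm = 0,
                        mass_lesion_volume_cm3 = 0, evacuated = FALSE,
                        epidural_mass_present = FALSE,
                        ivh_or_tsah_present = FALSE) {
  cistern_status <- match.arg(cistern_status, c("normal", "compressed", "absent"))
  stopifnot(midline_shift_mm >= 0, mass_lesion_volume_cm3 >= 0)
  structure(
    list(
      cistern_status = cistern_status,
      midline_shift_mm = as.numeric(midline_shift_mm),
      mass_lesion_volume_cm3 = as.numeric(mass_lesion_volume_cm3),
      evacuated = isTRUE(evacuated),
      epidural_mass_present = isTRUE(epidural_mass_present),
      ivh_or_tsah_present = isTRUE(ivh_or_tsah_present)
    ),
    class = "tbq_ct_findings"
  )
}

#' Marshall CT classification
#'
#' Six-class severity grading of the admission CT. Mass-lesion rules take
#' precedence: any surgically evacuated lesion is class V; a high/mixed
#' density lesion over 25 cm^3 not evacuated is class VI. Otherwise diffuse
#' injury grades I-IV follow cistern status and midline shift: I no visible
#' pathology; II cisterns present with shift of 5 mm or less; III cisterns
#' compressed or absent with shift of 5 mm or less; IV shift over 5 mm.
#'
#' @param f A [ct_findings()].
#' @return Ordered factor with levels `I` to `VI`.
#' @export
marshall <- function(f) {
  stopifnot(inherits(f, "tbq_ct_findings"))
  lv <- c("I", "II", "III", "IV", "V", "VI")
  big <- f$mass_lesion_volume_cm3 > 25
  cls <-
    if (f$evacuated) "V"
    else if (big) "VI"
    else if (f$midline_shift_mm > 5) "IV"
    else if (f$cistern_status != "normal") "III"
    else if (f$mass_lesion_volume_cm3 > 0 || f$midline_shift_mm > 0 ||
             f$epidural_mass_present || f$ivh_or_tsah_present) "II"
    else "I"
  factor(cls, levels = lv, ordered = TRUE)
}

#' Rotterdam CT score
#'
#' Additive score from 1 to 6:
#' 1 + cisterns (normal 0, compressed 1, absent 2) + (shift > 5 mm: 1) +
#' (epidural mass absent: 1) + (IVH or traumatic SAH present: 1).
#'
#' @param f A [ct_findings()].
#' @return Integer in 1..6.
#' @export
rotterdam <- function(f) {
  stopifnot(inherits(f, "tbq_ct_findings"))
  1L +
    c(normal = 0L, compressed = 1L, absent = 2L)[[f$cistern_status]] +
    (f$midline_shift_mm > 5) +
    (!f$epidural_mass_present) +
    f$ivh_or_tsah_present
}
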