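# Reporter-assay normalization: dual-luciferase (firefly/renilla), western
# densitometry (target/GAPDH) and Abeta ELISA, each expressed relative to
# the scrambled-control (SCR) miRNA within experiment. By construction the
# control group has mean exactly 1 in every normalization group, and all
# relative quantities are invariant to rescaling the denominator channel.

norm_groups <- function(data, extra = character()) {
  keys <- intersect(c("experiment", "construct", extra), names(data))
  if (!"experiment" %in% keys) {
    abort("Measurements need an 'experiment' column.", class = "polymirts_format_error")
  }
  keys
}

#' Relative dual-luciferase activity
#'
#' Per well, the transfection-efficiency-corrected ratio firefly/renilla
#' is divided by the mean ratio of the scrambled-control wells of the same
#' normalization group (experiment, and construct when present), so the
#' control group mean is exactly 1 per group.
#'
#' @param data Tibble with columns `experiment`, `mirna`, `firefly`,
#'   `renilla` and optionally `construct`.
#' @param control miRNA label of the scrambled control (default `"SCR"`).
#' @return `data` with columns `ratio` and `relative` added, classed
#'   `polymirts_relative`.
#' @export
relative_luciferase <- function(data, control = "SCR") {
  need <- c("experiment", "mirna", "firefly", "renilla")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("Luciferase data is missing columns: %s",
                  paste(missing, collapse = ", ")),
          class = "polymirts_format_error")
  }
  if (any(data$firefly <= 0) || any(data$renilla <= 0)) {
    abort("Firefly and renilla intensities must be positive.",
          class = "polymirts_format_error")
  }
  keys <- norm_groups(data)
  out <- dplyr::mutate(data, ratio = .data$firefly / .data$renilla)
  out <- dplyr::group_by(out, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::mutate(out, .scr_mean = {
    scr <- .data$ratio[.data$mirna == control]
    if (length(scr) == 0L) {
      abort(sprintf("A normalization group has no '%s' wells.", control),
            class = "polymirts_normalization_error")
    }
    mean(scr)
  })
  out <- dplyr::ungroup(dplyr::mutate(out, relative = .data$ratio / .data$.scr_mean))
  out$.scr_mean <- NULL
  class(out) <- c("polymirts_relative", class(tibble()))
  out
}

#' Relative densitometry (target band / GAPDH)
#'
#' Each band's intensity is divided by the GAPDH intensity of the same
#' (experiment, mirna) lane group, then normalized to the scrambled
#' control's ratio for that band within the experiment. With
#' `combine = "summed"` the mature and immature target bands are summed
#' before forming the ratio.
#'
#' @param data Tibble with columns `experiment`, `mirna`, `band`,
#'   `intensity`. GAPDH rows (`band == "GAPDH"`) are the loading control.
#' @param combine `"separate"` (default) or `"summed"` (sums bands named
#'   `NCSTN_mature` and `NCSTN_immature` into `NCSTN_total`).
#' @param control Scrambled-control miRNA label.
#' @return Tibble with one row per (experiment, mirna, band):
#'   `ratio` (band/GAPDH) and `relative` (ratio / control ratio).
#' @export
relative_densitometry <- function(data, combine = c("separate", "summed"),
                                  control = "SCR") {
  combine <- match.arg(combine)
  need <- c("experiment", "mirna", "band", "intensity")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("Densitometry data is missing columns: %s",
                  paste(missing, collapse = ", ")),
          class = "polymirts_format_error")
  }
  if (any(data$intensity <= 0)) {
    abort("Band intensities must be positive.", class = "polymirts_format_error")
  }
  if (combine == "summed") {
    is_ncstn <- data$band %in% c("NCSTN_mature", "NCSTN_immature")
    summed <- dplyr::summarise(
      dplyr::group_by(data[is_ncstn, ], .data$experiment, .data$mirna),
      band = "NCSTN_total", intensity = sum(.data$intensity), .groups = "drop"
    )
    data <- dplyr::bind_rows(data[!is_ncstn, ], summed)
  }
  gapdh <- dplyr::filter(data, .data$band == "GAPDH")
  if (nrow(gapdh) == 0L) {
    abort("No GAPDH loading-control bands present.",
          class = "polymirts_normalization_error")
  }
  gapdh <- dplyr::summarise(dplyr::group_by(gapdh, .data$experiment, .data$mirna),
                            .gapdh = mean(.data$intensity), .groups = "drop")
  out <- dplyr::left_join(dplyr::filter(data, .data$band != "GAPDH"),
                          gapdh, by = c("experiment", "mirna"))
  if (any(is.na(out$.gapdh))) {
    bad <- out[is.na(out$.gapdh), ][1, ]
    abort(sprintf("No GAPDH band for experiment '%s', miRNA '%s'.",
                  bad$experiment, bad$mirna),
          class = "polymirts_normalization_error")
  }
  out <- dplyr::mutate(out, ratio = .data$intensity / .data$.gapdh)
  out <- dplyr::group_by(out, .data$experiment, .data$band)
  out <- dplyr::mutate(out, .scr = {
    scr <- .data$ratio[.data$mirna == control]
    if (length(scr) == 0L) {
      abort(sprintf("No '%s' lane for a band group.", control),
            class = "polymirts_normalization_error")
    }
    mean(scr)
  })
  out <- dplyr::ungroup(dplyr::mutate(out, relative = .data$ratio / .data$.scr))
  out$.gapdh <- NULL; out$.scr <- NULL
  class(out) <- c("polymirts_relative", class(tibble()))
  out
}

#' Relative Abeta ELISA concentrations
#'
#' Concentrations are divided by the mean concentration of the scrambled
#' control within the same (experiment, analyte) group; Abeta40 and
#' Abeta42 are never mixed.
#'
#' @param data Tibble with columns `experiment`, `mirna`, `analyte`,
#'   `concentration`.
#' @param control Scrambled-control miRNA label.
#' @return `data` with a `relative` column added.
#' @export
relative_elisa <- function(data, control = "SCR") {
  need <- c("experiment", "mirna", "analyte", "concentration")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("ELISA data is missing columns: %s",
                  paste(missing, collapse = ", ")),
          class = "polymirts_format_error")
  }
  if (any(data$concentration < 0)) {
    abort("Concentrations must be non-negative.", class = "polymirts_format_error")
  }
  out <- dplyr::group_by(data, .data$experiment, .data$analyte)
  out <- dplyr::mutate(out, .scr = {
    scr <- .data$concentration[.data$mirna == control]
    if (length(scr) == 0L) {
      abort(sprintf("A (experiment, analyte) group has no '%s' wells.", control),
            class = "polymirts_normalization_error")
    }
    m <- mean(scr)
    if (m == 0) {
      abort("Control mean concentration is zero; cannot normalize.",
            class = "polymirts_normalization_error")
    }
    m
  })
  out <- dplyr::ungroup(dplyr::mutate(out, relative = .data$concentration / .data$.scr))
  out$.scr <- NULL
  class(out) <- c("polymirts_relative", class(tibble()))
  out
}
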