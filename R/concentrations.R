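#' Metabolite map types
#'
#' The pipeline builds maps for three metabolites (tCho, tCr, NAA) and two
#' diagnostic ratios (tCho/NAA, tCho/tCr).
#'
#' @return Character vector of the five map type names.
#' @export
map_types <- function() c("tCho", "tCr", "NAA", "tCho_over_NAA", "tCho_over_tCr")

ratio_types <- function() c("tCho_over_NAA", "tCho_over_tCr")

#' Literature-derived metabolite concentration table
#'
#' Concentration ranges (mM) and point estimates per tissue compartment for
#' the three mapped metabolites, plus tumor and nontumor ranges for the two
#' diagnostic ratios, as compiled from the in-vivo MRS literature. CSF is
#' treated as metabolite-free (concentration 0) and therefore carries no rows.
#'
#' Point estimates for the metabolite rows are the range midpoints; the
#' printed nontumor ratio estimates are kept as published even where they are
#' not exact midpoints (WM tCho/NAA 0.22; GM/WM tCho/tCr 0.80/0.50).
#'
#' @param values Optional replacement `data.frame` with columns
#'   `map_type`, `compartment` (GM/WM/Tumor), `lo`, `hi`, `estimate`.
#' @return A `data.frame` of class `concentration_table`.
#' @export
#' @examples
#' tab <- concentration_table()
#' subset(tab, map_type == "tCho")
concentration_table <- function(values = NULL) {
  if (is.null(values)) {
    values <- data.frame(
      map_type = rep(c("tCr", "tCho", "NAA", "tCho_over_NAA", "tCho_over_tCr"),
                     each = 3),
      compartment = rep(c("GM", "WM", "Tumor"), times = 5),
      lo = c(6.4, 5.2, 2.5,    1.6, 1.3, 2.5,    8.0, 6.0, 1.5,
             0.15, 0.14, 0.7,  0.40, 0.25, 0.5),
      hi = c(9.7, 5.7, 6.0,    2.0, 1.6, 5.5,    11.0, 9.0, 3.5,
             0.25, 0.28, 4.0,  1.40, 1.20, 3.0),
      estimate = c(8.05, 5.45, 4.25,  1.8, 1.45, 4.00,  9.5, 7.5, 2.50,
                   0.20, 0.22, 2.35,  0.80, 0.50, 1.75),
      stringsAsFactors = FALSE
    )
  }
  req <- c("map_type", "compartment", "lo", "hi", "estimate")
  if (!all(req %in% names(values))) stop_invalid("table needs columns: ",
                                                 paste(req, collapse = ", "))
  if (any(values$lo > values$hi)) stop_invalid("table has lo > hi")
  if (any(values$estimate < values$lo | values$estimate > values$hi))
    stop_invalid("table estimate outside its range")
  if (any(values$lo <= 0)) stop_invalid("all concentrations must be > 0 (CSF is implicit)")
  class(values) <- c("concentration_table", "data.frame")
  values
}

#' Read a concentration table override from a YAML config
#'
#' The YAML file holds a list of records with fields `map_type`,
#' `compartment`, `lo`, `hi` and optional `estimate` (defaults to the range
#' midpoint).
#'
#' @param path YAML file path.
#' @return A `concentration_table`.
#' @export
read_concentration_table <- function(path) {
  recs <- yaml::read_yaml(path)
  df <- do.call(rbind, lapply(recs, function(r) {
    data.frame(map_type = r$map_type, compartment = r$compartment,
               lo = r$lo, hi = r$hi,
               estimate = if (is.null(r$estimate)) (r$lo + r$hi) / 2 else r$estimate,
               stringsAsFactors = FALSE)
  }))
  concentration_table(df)
}

table_lookup <- function(table, map_type, compartment) {
  row <- table[table$map_type == map_type & table$compartment == compartment, ]
  if (nrow(row) != 1)
    stop_invalid("no table entry for ", map_type, " / ", compartment)
  row
}

#' Point estimate of a concentration range
#'
#' The estimated concentration associated with a literature range is its
#' midpoint, `(lo + hi) / 2`.
#'
#' @param lo,hi Range endpoints (mM or ratio units), `lo <= hi`. Vectorized.
#' @return Midpoint(s).
#' @export
#' @examples
#' estimated_concentration(2.5, 5.5)  # tumor tCho -> 4.00
estimated_concentration <- function(lo, hi) {
  if (any(lo > hi)) stop_invalid("lo must be <= hi")
  (lo + hi) / 2
}

#' Tumor-grade threshold for a ratio range
#'
#' Lower-grade (LGG) tumor ratio values are drawn from below this threshold
#' and high-grade (HGG) values from above it; the threshold is the average of
#' the reported range.
#'
#' @inheritParams estimated_concentration
#' @return The threshold value(s).
#' @export
#' @examples
#' grade_threshold(0.7, 4.0)  # tCho/NAA -> 2.35
grade_threshold <- function(lo, hi) {
  if (any(lo > hi)) stop_invalid("lo must be <= hi")
  (lo + hi) / 2
}

#' Tumor-compartment value for a map type
#'
#' For ratio maps the tumor range is split at [grade_threshold()]: LGG values
#' live in the lower sub-range, HGG in the upper. In `"deterministic"` mode
#' the midpoint of the grade's sub-range is returned for ratios and the
#' table's tumor estimate for metabolites; in `"sampled"` mode a seeded
#' uniform draw from the grade's sub-range (ratios) or the full tumor range
#' (metabolites) is returned.
#'
#' @param table A [concentration_table()].
#' @param map_type One of [map_types()].
#' @param grade `"LGG"` or `"HGG"`.
#' @param mode `"deterministic"` or `"sampled"`.
#' @param seed Seed used in sampled mode.
#' @return A single concentration or ratio value.
#' @export
#' @examples
#' tumor_value(concentration_table(), "tCho_over_NAA", "HGG")  # 3.175
tumor_value <- function(table, map_type, grade = c("HGG", "LGG"),
                        mode = c("deterministic", "sampled"), seed = 1L) {
  grade <- match.arg(grade)
  mode <- match.arg(mode)
  if (!map_type %in% map_types())
    stop_invalid("unknown map_type '", map_type, "'; valid: ",
                 paste(map_types(), collapse = ", "))
  row <- table_lookup(table, map_type, "Tumor")
  if (map_type %in% ratio_types()) {
    thr <- grade_threshold(row$lo, row$hi)
    rng <- if (grade == "LGG") c(row$lo, thr) else c(thr, row$hi)
  } else {
    rng <- c(row$lo, row$hi)
  }
  if (mode == "deterministic") {
    if (map_type %in% ratio_types()) mean(rng) else row$estimate
  } else {
    with_seed(seed, stats::runif(1, rng[1], rng[2]))
  }
}
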