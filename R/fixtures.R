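#' Convert a standard error to a sampling standard deviation
#'
#' Published trait tables report per-treatment means with standard errors;
#' recovering the plant-to-plant standard deviation needs the replicate
#' count, \code{sd = se * sqrt(n)}.
#'
#' @param se Standard error(s), non-negative.
#' @param n Number of replicates the SE was computed from (positive integer).
#' @return Numeric vector of standard deviations, same length as `se`.
#' @examples
#' sd_from_se(11, 4)      # 22
#' sd_from_se(0.0017, 4)  # 0.0034
#' @export
sd_from_se <- function(se, n) {
  if (!is.numeric(se) || any(!is.finite(se)) || any(se < 0)) {
    stop("`se` must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 ||
      n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  se * sqrt(n)
}

# One root type's published rows: trait token, unit, then mean/se/letters for
# Control, Drought, Heat, Combined in that fixed order.
.fixture_block <- function(root_type, rows) {
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      root_type = root_type,
      trait = r[[1L]],
      unit = r[[2L]],
      treatment = c("Control", "Drought", "Heat", "Combined"),
      mean = as.numeric(r[[3L]]),
      se = as.numeric(r[[4L]]),
      letters = as.character(r[[5L]]),
      stringsAsFactors = FALSE
    )
  }))
  out$n <- 4L
  out
}

#' Built-in per-treatment trait summaries for maize root types
#'
#' Cell values (mean, standard error with n = 4, and the published Tukey
#' letter codes) for each root morphological trait of the four maize root
#' types -- primary and seminal axes and their laterals -- under Control,
#' Drought (30\% field capacity), Heat (32 degrees C) and Combined
#' (drought + heat) treatments. These summaries calibrate the synthetic-data
#' generator and provide deterministic worked examples for the
#' effect-size machinery.
#'
#' Traits carry field-standard meanings: `rlr` root length ratio
#' (cm g-1, root length over whole-plant dry weight), `rmr` root mass ratio
#' (g g-1), `fineness` root length per root volume (cm cm-3),
#' `tissue_density` root dry weight per volume (g cm-3),
#' `branching_density` laterals per cm of branching zone (axes only),
#' `root_zone`/`branching_zone` zone lengths along the axis (cm),
#' `number` lateral-root count and `average_length` mean lateral length
#' (cm, lateral types only).
#'
#' @return A data.frame with columns `root_type`, `trait`, `unit`,
#'   `treatment`, `mean`, `se`, `letters`, `n`; one row per
#'   root type x trait x treatment cell (168 rows: 11 + 11 + 10 + 10 traits).
#' @examples
#' fx <- builtin_table_fixtures()
#' subset(fx, root_type == "primary" & trait == "fineness")
#' @export
builtin_table_fixtures <- function() {
  primary <- list(
    list("fresh_weight", "g",
         c(0.128, 0.131, 0.147, 0.162),
         c(0.008, 0.001, 0.001, 0.021),
         c("a", "a", "a", "a")),
    list("dry_weight", "g",
         c(0.0111, 0.0116, 0.0131, 0.0168),
         c(0.0009, 0.0006, 0.0003, 0.0017),
         c("b", "b", "b", "a")),
    list("length", "cm",
         c(49, 71, 57, 66), c(1, 6, 4, 12),
         c("a", "a", "a", "a")),
    list("surface_area", "cm2",
         c(9.460, 10.669, 9.723, 10.415),
         c(0.009, 0.896, 0.587, 1.766),
         c("a", "a", "a", "a")),
    list("rlr", "cm/g",
         c(63, 123, 83, 117), c(4, 12, 2, 15),
         c("b", "a", "b", "a")),
    list("rmr", "g/g",
         c(0.01381, 0.01840, 0.02004, 0.02702),
         c(0.00016, 0.00002, 0.00051, 0.00205),
         c("c", "b", "b", "a")),
    list("fineness", "cm/cm3",
         c(336, 531, 396, 500), c(11, 11, 8, 6),
         c("c", "a", "b", "a")),
    list("tissue_density", "g/cm3",
         c(0.075, 0.097, 0.097, 0.117),
         c(0.007, 0.006, 0.003, 0.007),
         c("c", "b", "b", "a")),
    list("root_zone", "cm",
         c(9, 3, 9, 7), c(1, 1, 3, 1),
         c("a,b", "b", "a", "a,b")),
    list("branching_zone", "cm",
         c(42, 65, 48, 64), c(2, 5, 1, 11),
         c("b", "a", "a,b", "a")),
    list("branching_density", "n/cm",
         c(4.961, 3.389, 4.276, 4.152),
         c(0.101, 0.051, 0.027, 0.284),
         c("a", "c", "b", "b"))
  )
  seminal <- list(
    list("fresh_weight", "g",
         c(0.285, 0.172, 0.205, 0.176),
         c(0.031, 0.029, 0.043, 0.018),
         c("a", "b", "a,b", "b")),
    list("dry_weight", "g",
         c(0.021, 0.015, 0.014, 0.018),
         c(0.004, 0.003, 0.004, 0.002),
         c("a", "a", "a", "a")),
    list("length", "cm",
         c(64, 64, 63, 51), c(7, 7, 8, 2),
         c("a", "a", "a", "a")),
    list("surface_area", "cm2",
         c(11, 10, 12, 10), c(1, 1, 2, 1),
         c("a", "a", "a", "a")),
    list("rlr", "cm/g",
         c(82, 103, 97, 83), c(13, 14, 14, 1),
         c("a", "a", "a", "a")),
    list("rmr", "g/g",
         c(0.027, 0.023, 0.027, 0.031),
         c(0.002, 0.002, 0.007, 0.003),
         c("a", "a", "a", "a")),
    list("fineness", "cm/cm3",
         c(294, 463, 435, 362), c(47, 21, 55, 24),
         c("b", "a", "a", "a,b")),
    list("tissue_density", "g/cm3",
         c(0.094, 0.064, 0.091, 0.124),
         c(0.007, 0.023, 0.003, 0.001),
         c("a,b", "b", "a,b", "a")),
    list("root_zone", "cm",
         c(7, 8, 12, 6), c(1, 2, 3, 1),
         c("a,b", "a,b", "a", "b")),
    list("branching_zone", "cm",
         c(54, 55, 57, 44), c(5, 6, 14, 3),
         c("a", "a", "a", "a")),
    list("branching_density", "n/cm",
         c(2.8, 2.9, 4.5, 3.0), c(0.1, 0.1, 0.4, 0.2),
         c("b", "b", "a", "b"))
  )
  primary_lateral <- list(
    list("fresh_weight", "g",
         c(0.212, 0.280, 0.315, 0.225),
         c(0.012, 0.047, 0.040, 0.001),
         c("b", "a,b", "a", "a,b")),
    list("dry_weight", "g",
         c(0.022, 0.016, 0.021, 0.020),
         c(0.004, 0.001, 0.003, 0.001),
         c("a", "a", "a", "a")),
    list("length", "cm",
         c(557, 691, 757, 1028), c(8, 35, 82, 33),
         c("c", "b,c", "b", "a")),
    list("surface_area", "cm2",
         c(34.6, 37.2, 45.8, 53.3),
         c(0.7, 2.7, 4.8, 0.1),
         c("b", "b", "a", "a")),
    list("number", "n",
         c(208, 225, 200, 247), c(16, 14, 2, 27),
         c("a", "a", "a", "a")),
    list("average_length", "cm",
         c(2.860, 3.076, 3.640, 4.486),
         c(0.136, 0.039, 0.384, 0.578),
         c("b", "b", "a,b", "a")),
    list("rlr", "cm/g",
         c(736, 1195, 1125, 1650), c(41, 63, 75, 90),
         c("c", "b", "b", "a")),
    list("rmr", "g/g",
         c(0.0324, 0.0220, 0.0308, 0.0330),
         c(0.0079, 0.0003, 0.0031, 0.0016),
         c("a", "a", "a", "a")),
    list("fineness", "cm/cm3",
         c(3257, 4018, 3512, 4670), c(44, 56, 76, 288),
         c("c", "b", "c", "a")),
    list("tissue_density", "g/cm3",
         c(0.134, 0.093, 0.097, 0.093),
         c(0.027, 0.005, 0.005, 0.006),
         c("a", "a", "a", "a"))
  )
  seminal_lateral <- list(
    list("fresh_weight", "g",
         c(0.0600, 0.0355, 0.1323, 0.0149),
         c(0.0114, 0.0048, 0.0459, 0.0002),
         c("a,b", "b", "a", "b")),
    list("dry_weight", "g",
         c(0.0051, 0.0035, 0.0025, 0.0013),
         c(0.0010, 0.0006, 0.0008, 0.0002),
         c("a", "a,b", "b", "b")),
    list("length", "cm",
         c(113, 104, 105, 79), c(7, 1, 13, 14),
         c("a", "a,b", "a,b", "b")),
    list("surface_area", "cm2",
         c(8.5, 7.5, 3.7, 4.5), c(1.3, 0.1, 0.6, 0.9),
         c("a", "a", "b", "b")),
    list("number", "n",
         c(149, 169, 202, 134), c(21, 18, 23, 5),
         c("a,b", "a,b", "a", "b")),
    list("average_length", "cm",
         c(0.872, 0.707, 0.563, 0.530),
         c(0.151, 0.081, 0.136, 0.094),
         c("a", "a", "a", "a")),
    list("rlr", "cm/g",
         c(147, 178, 151, 128), c(1, 2, 12, 19),
         c("a,b", "a", "a,b", "b")),
    list("rmr", "g/g",
         c(0.0066, 0.0032, 0.0041, 0.0021),
         c(0.0010, 0.0001, 0.0015, 0.0003),
         c("a", "b", "a,b", "b")),
    list("fineness", "cm/cm3",
         c(2728, 2416, 3630, 6283), c(48, 0, 376, 1176),
         c("b", "b", "b", "a")),
    list("tissue_density", "g/cm3",
         c(0.095, 0.085, 0.101, 0.102),
         c(0.004, 0.015, 0.036, 0.022),
         c("a", "a", "a", "a"))
  )
  rbind(
    .fixture_block("primary", primary),
    .fixture_block("seminal", seminal),
    .fixture_block("primary_lateral", primary_lateral),
    .fixture_block("seminal_lateral", seminal_lateral)
  )
}

#' Root types recognised by the pipeline
#' @return Character vector of the four maize root types.
#' @export
root_types <- function() {
  c("primary", "seminal", "primary_lateral", "seminal_lateral")
}

#' Treatment labels in canonical order
#' @return Character vector: Control, Drought, Heat, Combined.
#' @export
treatment_levels <- function() {
  c("Control", "Drought", "Heat", "Combined")
}

#' Percent change of treatment means relative to a reference treatment
#'
#' Computes \code{100 * (mean_treatment - mean_reference) / mean_reference}
#' per root type x trait from a treatment summary table (either the built-in
#' published cells or [summarize_treatments()] output).
#'
#' @param summary Data.frame with columns `root_type`, `trait`, `treatment`,
#'   `mean` (e.g. [builtin_table_fixtures()]).
#' @param treatment Treatment whose change is reported (default "Combined").
#' @param reference Baseline treatment (default "Control").
#' @return Data.frame `root_type`, `trait`, `mean_reference`,
#'   `mean_treatment`, `pct_change`.
#' @examples
#' pc <- percent_change(builtin_table_fixtures())
#' subset(pc, root_type == "primary_lateral" & trait == "rlr")
#' @export
percent_change <- function(summary, treatment = "Combined",
                           reference = "Control") {
  stopifnot(is.data.frame(summary),
            all(c("root_type", "trait", "treatment", "mean") %in%
                  names(summary)))
  if (!treatment %in% summary$treatment || !reference %in% summary$treatment) {
    stop("requested treatments absent from summary", call. = FALSE)
  }
  trt <- summary[summary$treatment == treatment, ]
  ref <- summary[summary$treatment == reference, ]
  key <- function(d) paste(d$root_type, d$trait, sep = "\r")
  m <- match(key(trt), key(ref))
  if (anyNA(m)) stop("reference cells missing for some traits", call. = FALSE)
  ref <- ref[m, ]
  if (any(ref$mean == 0)) stop("zero reference mean", call. = FALSE)
  data.frame(
    root_type = trt$root_type,
    trait = trt$trait,
    mean_reference = ref$mean,
    mean_treatment = trt$mean,
    pct_change = 100 * (trt$mean - ref$mean) / ref$mean,
    stringsAsFactors = FALSE
  )
}
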