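#' Configure the synthetic factorial dataset generator
#'
#' Describes a randomized complete design -- a set of treatments with a fixed
#' number of replicate plants each -- together with the per-treatment trait
#' means and standard errors the generated plants should reproduce. The
#' default specs are the built-in published cell values, so the default
#' configuration emulates the study design: 4 treatments x 4 replicates,
#' 4 root types.
#'
#' @param seed Integer seed; mandatory, fully determines the output.
#' @param treatments Ordered, unique treatment labels.
#' @param n_per_treatment Replicate plants per treatment (>= 2).
#' @param mode `"trait_level"` draws each derived trait directly from its
#'   configured normal law; `"raw_level"` draws raw measurements (lengths,
#'   volumes, weights, counts, zone lengths) from which derived traits are
#'   computed, so the algebraic identities among traits hold exactly.
#' @param specs Data.frame of trait specifications in the layout of
#'   [builtin_table_fixtures()]: `root_type`, `trait`, `treatment`, `mean`,
#'   `se`, `n` (the `n` the SE was computed from, used to recover the SD).
#' @param root_types Root types to generate (subset of `specs$root_type`).
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed,
                             treatments = treatment_levels(),
                             n_per_treatment = 4L,
                             mode = c("trait_level", "raw_level"),
                             specs = builtin_table_fixtures(),
                             root_types = unique(specs$root_type)) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed) || !is.numeric(seed) ||
      length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` is mandatory and must be a single finite number",
         call. = FALSE)
  }
  if (anyDuplicated(treatments)) {
    stop("treatment labels must be unique", call. = FALSE)
  }
  if (!is.numeric(n_per_treatment) || n_per_treatment < 2) {
    stop("`n_per_treatment` must be >= 2", call. = FALSE)
  }
  stopifnot(is.data.frame(specs),
            all(c("root_type", "trait", "treatment", "mean", "se", "n") %in%
                  names(specs)))
  if (any(specs$se < 0) || any(specs$n < 2)) {
    stop("specs need se >= 0 and n >= 2", call. = FALSE)
  }
  missing_trt <- setdiff(treatments, unique(specs$treatment))
  if (length(missing_trt)) {
    stop("no specs for treatment(s): ", paste(missing_trt, collapse = ", "),
         call. = FALSE)
  }
  missing_rt <- setdiff(root_types, unique(specs$root_type))
  if (length(missing_rt)) {
    stop("no specs for root type(s): ", paste(missing_rt, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed),
         treatments = as.character(treatments),
         n_per_treatment = as.integer(n_per_treatment),
         mode = mode,
         specs = specs[specs$treatment %in% treatments &
                         specs$root_type %in% root_types, , drop = FALSE],
         root_types = as.character(root_types)),
    class = "synthetic_config"
  )
}

# Normal draws truncated to the positive half-line by resampling.
# sd = 0 degenerates to the (positive) mean.
.rnorm_pos <- function(n, mean, sd) {
  if (mean <= 0) stop("truncated-normal mean must be positive", call. = FALSE)
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x <= 0
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  stop("could not draw positive values (mean << sd?)", call. = FALSE)
}

.plant_ids <- function(treatment, n) {
  sprintf("P%s%02d", substr(treatment, 1, 4), seq_len(n))
}

#' Generate a synthetic per-plant trait dataset
#'
#' Draws a seeded dataset in the configured design. In `trait_level` mode each
#' plant's trait value is an independent normal draw with the spec's mean and
#' `sd_from_se(se, n)`, resampled until positive. In `raw_level` mode the
#' generator fixes each plant's whole-plant dry weight first, then draws raw
#' root measurements per root type so that derived traits are centred on the
#' configured values; derived traits are computed through [derive_dataset()]
#' and therefore satisfy the length-ratio decomposition identity exactly.
#' Identical configurations (including seed) give identical datasets.
#'
#' @param config A [synthetic_config()].
#' @return Tidy data.frame of class `"plant_dataset"` with columns
#'   `plant_id`, `treatment`, `root_type`, `trait`, `value`. In raw mode the
#'   raw measurement tables are attached as attributes `"raw_roots"` and
#'   `"raw_plants"`.
#' @examples
#' d <- generate_dataset(synthetic_config(seed = 1, n_per_treatment = 4))
#' head(d)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("`config` must come from synthetic_config()", call. = FALSE)
  }
  set.seed(config$seed)
  out <- if (config$mode == "trait_level") {
    .generate_trait_level(config)
  } else {
    .generate_raw_level(config)
  }
  class(out) <- c("plant_dataset", class(out))
  out
}

.generate_trait_level <- function(config) {
  sp <- config$specs
  sp <- sp[order(match(sp$treatment, config$treatments),
                 match(sp$root_type, unique(sp$root_type)), sp$trait), ]
  rows <- lapply(config$treatments, function(trt) {
    ids <- .plant_ids(trt, config$n_per_treatment)
    sub <- sp[sp$treatment == trt, ]
    do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
      vals <- .rnorm_pos(config$n_per_treatment, sub$mean[i],
                         sd_from_se(sub$se[i], sub$n[i]))
      data.frame(plant_id = ids, treatment = trt,
                 root_type = sub$root_type[i], trait = sub$trait[i],
                 value = vals, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

# One spec cell: mean/se/n for (treatment, root type, trait); NA if absent.
.cell <- function(sp, rt, tr) {
  i <- which(sp$root_type == rt & sp$trait == tr)
  if (!length(i)) return(NULL)
  list(mean = sp$mean[i[1L]], sd = sd_from_se(sp$se[i[1L]], sp$n[i[1L]]))
}

.generate_raw_level <- function(config) {
  axes <- c("primary", "seminal")
  raw_roots <- NULL
  raw_plants <- NULL
  for (trt in config$treatments) {
    sp <- config$specs[config$specs$treatment == trt, ]
    n <- config$n_per_treatment
    ids <- .plant_ids(trt, n)
    # whole-plant dry weight target: mean over root types of DW/RMR
    pdw_est <- vapply(config$root_types, function(rt) {
      dw <- .cell(sp, rt, "dry_weight"); rmr <- .cell(sp, rt, "rmr")
      if (is.null(dw) || is.null(rmr)) NA_real_ else dw$mean / rmr$mean
    }, numeric(1))
    pdw_mean <- mean(pdw_est, na.rm = TRUE)
    if (!is.finite(pdw_mean)) {
      stop("raw_level mode needs dry_weight and rmr specs", call. = FALSE)
    }
    pdw <- .rnorm_pos(n, pdw_mean, 0.10 * pdw_mean)
    for (rt in config$root_types) {
      need <- c("rmr", "rlr", "fineness", "fresh_weight")
      miss <- need[vapply(need, function(tr) is.null(.cell(sp, rt, tr)),
                          logical(1))]
      if (length(miss)) {
        stop("raw_level mode: missing spec for ", rt, ": ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      rmr <- .cell(sp, rt, "rmr"); rlr <- .cell(sp, rt, "rlr")
      fin <- .cell(sp, rt, "fineness"); fw <- .cell(sp, rt, "fresh_weight")
      dw_i <- pdw * .rnorm_pos(n, rmr$mean, rmr$sd)
      len_i <- pdw * .rnorm_pos(n, rlr$mean, rlr$sd)
      vol_i <- len_i / .rnorm_pos(n, fin$mean, fin$sd)
      fw_i <- pmax(.rnorm_pos(n, fw$mean, fw$sd), dw_i * 1.05)
      sa <- .cell(sp, rt, "surface_area")
      sa_i <- if (is.null(sa)) rep(NA_real_, n) else .rnorm_pos(n, sa$mean, sa$sd)
      if (rt %in% axes) {
        bz <- .cell(sp, rt, "branching_zone")
        rz <- .cell(sp, rt, "root_zone")
        bd <- .cell(sp, rt, "branching_density")
        if (is.null(bz) || is.null(rz) || is.null(bd)) {
          stop("raw_level mode: axis ", rt,
               " needs branching_zone, root_zone, branching_density specs",
               call. = FALSE)
        }
        bzf_i <- pmin(.rnorm_pos(n, bz$mean, bz$sd), 0.95 * len_i)
        rzf_i <- pmin(.rnorm_pos(n, rz$mean, rz$sd), len_i - bzf_i)
        cnt_i <- pmax(1, round(.rnorm_pos(n, bd$mean, bd$sd) * bzf_i))
      } else {
        nc <- .cell(sp, rt, "number")
        if (is.null(nc)) {
          stop("raw_level mode: lateral ", rt, " needs a number spec",
               call. = FALSE)
        }
        cnt_i <- pmax(1, round(.rnorm_pos(n, nc$mean, nc$sd)))
        bzf_i <- rep(NA_real_, n)
        rzf_i <- rep(NA_real_, n)
      }
      raw_roots <- rbind(raw_roots, data.frame(
        plant_id = ids, treatment = trt, root_type = rt,
        length = len_i, surface_area = sa_i, volume = vol_i,
        fresh_weight = fw_i, dry_weight = dw_i,
        lateral_count = as.integer(cnt_i),
        root_zone = rzf_i, branching_zone = bzf_i,
        stringsAsFactors = FALSE
      ))
    }
    rdw <- tapply(raw_roots$dry_weight[raw_roots$treatment == trt],
                  raw_roots$plant_id[raw_roots$treatment == trt], sum)[ids]
    rfw <- tapply(raw_roots$fresh_weight[raw_roots$treatment == trt],
                  raw_roots$plant_id[raw_roots$treatment == trt], sum)[ids]
    shdw <- pmax(pdw - rdw, 0.05 * pdw)
    raw_plants <- rbind(raw_plants, data.frame(
      plant_id = ids, treatment = trt,
      shoot_dry_weight = as.numeric(shdw),
      shoot_fresh_weight = as.numeric(9 * shdw),
      stringsAsFactors = FALSE
    ))
  }
  rownames(raw_roots) <- NULL
  out <- derive_dataset(raw_roots, raw_plants)
  attr(out, "raw_roots") <- raw_roots
  attr(out, "raw_plants") <- raw_plants
  out
}

#' Summarize a plant dataset into per-treatment trait means and SEs
#'
#' The tabular content of a published treatment-summary table: per
#' root type x trait x treatment, the replicate mean, standard error and n.
#'
#' @param dataset Tidy `plant_dataset` data.frame.
#' @return Data.frame `root_type`, `trait`, `treatment`, `mean`, `se`, `n`.
#' @export
summarize_treatments <- function(dataset) {
  .check_dataset(dataset)
  key <- interaction(dataset$root_type, dataset$trait, dataset$treatment,
                     drop = TRUE, lex.order = TRUE)
  agg <- do.call(rbind, lapply(split(dataset, key), function(d) {
    data.frame(root_type = d$root_type[1L], trait = d$trait[1L],
               treatment = d$treatment[1L], mean = mean(d$value),
               se = stats::sd(d$value) / sqrt(nrow(d)), n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}

.check_dataset <- function(dataset) {
  stopifnot(is.data.frame(dataset))
  need <- c("plant_id", "treatment", "root_type", "trait", "value")
  miss <- setdiff(need, names(dataset))
  if (length(miss)) {
    stop("dataset lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(dataset$value))) {
    stop("dataset has non-finite trait values", call. = FALSE)
  }
  dup <- duplicated(dataset[c("plant_id", "root_type", "trait")])
  if (any(dup)) {
    stop("duplicate (plant_id, root_type, trait) records", call. = FALSE)
  }
  invisible(dataset)
}

#' Pivot a tidy plant dataset to a wide trait matrix
#'
#' One row per plant, one column per `root_type.trait` combination; the
#' sample layout multivariate stages (PERMANOVA, sPLS-DA) consume.
#'
#' @param dataset Tidy `plant_dataset` data.frame.
#' @param traits Optional character vector of trait tokens to keep.
#' @param root_types Optional character vector of root types to keep.
#' @param complete Drop columns with any missing cell (default TRUE).
#' @return Data.frame: `plant_id`, `treatment`, then one numeric column per
#'   `root_type.trait`.
#' @export
trait_matrix <- function(dataset, traits = NULL, root_types = NULL,
                         complete = TRUE) {
  .check_dataset(dataset)
  d <- dataset
  if (!is.null(traits)) d <- d[d$trait %in% traits, ]
  if (!is.null(root_types)) d <- d[d$root_type %in% root_types, ]
  if (!nrow(d)) stop("no records left after filtering", call. = FALSE)
  d$column <- paste(d$root_type, d$trait, sep = ".")
  plants <- unique(d[c("plant_id", "treatment")])
  cols <- unique(d$column)
  m <- matrix(NA_real_, nrow(plants), length(cols),
              dimnames = list(plants$plant_id, cols))
  m[cbind(match(d$plant_id, plants$plant_id), match(d$column, cols))] <- d$value
  if (complete) {
    keep <- colSums(is.na(m)) == 0L
    m <- m[, keep, drop = FALSE]
  }
  cbind(plants, as.data.frame(m), stringsAsFactors = FALSE)
}

#' Write / read the tidy per-plant CSV dialect
#'
#' @param dataset Tidy `plant_dataset` data.frame.
#' @param path File path.
#' @return `write_dataset_csv` returns `path` invisibly; `read_dataset_csv`
#'   returns a validated `plant_dataset` data.frame.
#' @export
write_dataset_csv <- function(dataset, path) {
  .check_dataset(dataset)
  utils::write.csv(as.data.frame(dataset)[
    c("plant_id", "treatment", "root_type", "trait", "value")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_dataset(d)
  class(d) <- c("plant_dataset", class(d))
  d
}
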