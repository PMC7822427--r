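#' Build a validated pipeline run configuration
#'
#' Collects everything a full analysis run needs: the input dataset (a tidy
#' CSV path or a [synthetic_config()]), the significance level, permutation
#' and cross-validation settings, the trait set entering the multivariate
#' stages, the seed and the output directory.
#'
#' @param seed Integer seed (mandatory; every stochastic stage derives its
#'   stream from it).
#' @param output_dir Directory the report bundle is written to.
#' @param input Path to a tidy per-plant CSV, or NULL to simulate.
#' @param synthetic A [synthetic_config()] used when `input` is NULL
#'   (default: built-in calibrated design with this config's seed).
#' @param alpha Significance level in (0, 1).
#' @param n_permutations PERMANOVA permutations (>= 99).
#' @param folds,repeats Cross-validation folds and repeats for sPLS-DA.
#' @param max_ncomp Largest component count assessed.
#' @param keepX_grid Candidate traits-per-component grid (NULL = default).
#' @param traits,root_types Optional trait-set restriction for the
#'   multivariate stages.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed, output_dir, input = NULL, synthetic = NULL,
                       alpha = 0.05, n_permutations = 999, folds = 5L,
                       repeats = 50L, max_ncomp = 5L, keepX_grid = NULL,
                       traits = NULL, root_types = NULL) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory", call. = FALSE)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (n_permutations < 99) {
    stop("`n_permutations` must be >= 99", call. = FALSE)
  }
  if (is.null(input) && is.null(synthetic)) {
    synthetic <- synthetic_config(seed = seed)
  }
  structure(list(
    seed = as.integer(seed), output_dir = output_dir, input = input,
    synthetic = synthetic, alpha = alpha,
    n_permutations = as.integer(n_permutations), folds = as.integer(folds),
    repeats = as.integer(repeats), max_ncomp = as.integer(max_ncomp),
    keepX_grid = keepX_grid, traits = traits, root_types = root_types
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`); keys mirror the
#'   arguments of [run_config()]; `seed` is mandatory.
#' @param output_dir Optional override of the file's `output_dir`.
#' @return A validated `"run_config"`.
#' @export
read_run_config <- function(path, output_dir = NULL) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(output_dir)) raw$output_dir <- output_dir
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Sequences the whole analysis on one dataset: simulate or load the tidy
#' per-plant table, univariate screen with Tukey letters, interaction
#' classification of the traits the combined stress modified, PERMANOVA with
#' pairwise FDR-corrected contrasts, sPLS-DA with component and variable
#' selection, and Pearson correlations of the latent scores with plant
#' weights. All report families are written as CSV under
#' `config$output_dir`, plus a JSON manifest holding the configuration,
#' seeds and versions; identical config and seed give an identical bundle.
#' Every reported number is computed by the corresponding module function.
#'
#' @param config A [run_config()].
#' @param verbose Log stage progress to stderr (default TRUE).
#' @return Invisible list with the in-memory results: `dataset`, `screen`,
#'   `interaction`, `permanova`, `pairwise`, `perf`, `tune`, `model`,
#'   `correlations`, `manifest`.
#' @export
run_all <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message("[rootstress] ", ...)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)

  say("stage 1/5: dataset")
  dataset <- if (!is.null(config$input)) {
    read_dataset_csv(config$input)
  } else {
    generate_dataset(config$synthetic)
  }
  write_dataset_csv(dataset, out("dataset.csv"))

  say("stage 2/5: univariate screen")
  screen <- trait_screen(dataset, alpha = config$alpha)
  utils::write.csv(screen$anova, out("univariate_anova.csv"),
                   row.names = FALSE)
  utils::write.csv(format_screen_table(screen), out("univariate_tables.csv"),
                   row.names = FALSE)

  say("stage 3/5: interaction classification")
  inter <- interaction_screen(dataset, alpha = config$alpha)
  if (!is.null(inter)) {
    utils::write.csv(inter, out("interaction_report.csv"), row.names = FALSE)
  }

  say("stage 4/5: PERMANOVA")
  wide <- trait_matrix(dataset, traits = config$traits,
                       root_types = config$root_types %||%
                         setdiff(unique(dataset$root_type), "plant"))
  Xdf <- wide[setdiff(names(wide), c("plant_id", "treatment"))]
  X <- as.matrix(Xdf)
  rownames(X) <- wide$plant_id
  d <- standardize_and_distance(X)
  pv <- permanova(d, wide$treatment,
                  n_permutations = config$n_permutations,
                  seed = config$seed + 1000L)
  pw <- pairwise_permanova(d, wide$treatment,
                           n_permutations = config$n_permutations,
                           seed = config$seed + 2000L)
  utils::write.csv(data.frame(
    term = c("Stress treatment", "Residual", "Total"),
    df = c(pv$df_treatment, pv$df_residual, pv$df_total),
    R2 = c(pv$R2, 1 - pv$R2, 1),
    pseudo_F = c(pv$pseudo_F, NA, NA), p = c(pv$p, NA, NA)),
    out("permanova.csv"), row.names = FALSE)
  utils::write.csv(pw, out("permanova_pairwise.csv"), row.names = FALSE)

  say("stage 5/5: sPLS-DA")
  max_ncomp <- min(config$max_ncomp, ncol(X), nrow(X) - 1L)
  cv <- perf(X, wide$treatment, max_ncomp = max_ncomp,
             folds = config$folds, repeats = config$repeats,
             seed = config$seed + 3000L)
  utils::write.csv(cv, out("splsda_perf.csv"), row.names = FALSE)
  ncomp_use <- min(3L, max_ncomp)
  tn <- tune(X, wide$treatment, ncomp = ncomp_use,
             keepX_grid = config$keepX_grid, folds = config$folds,
             repeats = config$repeats, seed = config$seed + 4000L)
  model <- fit_splsda(X, wide$treatment, ncomp = ncomp_use, keepX = tn$keepX)
  write_splsda_json(model, out("splsda_model.json"))
  utils::write.csv(
    data.frame(plant_id = wide$plant_id, treatment = wide$treatment,
               model$scores),
    out("splsda_scores.csv"), row.names = FALSE)
  loadings <- do.call(rbind, lapply(seq_len(ncomp_use), function(h) {
    lg <- loading_group_assignment(model, X, wide$treatment, h)
    if (is.null(lg) || !nrow(lg)) return(NULL)
    cbind(component = h, lg)
  }))
  utils::write.csv(loadings, out("splsda_loadings.csv"), row.names = FALSE)
  corr <- NULL
  for (wtrait in c("plant_fresh_weight", "plant_dry_weight")) {
    wv <- dataset[dataset$root_type == "plant" & dataset$trait == wtrait, ]
    if (!nrow(wv)) next
    v <- stats::setNames(wv$value, wv$plant_id)[wide$plant_id]
    if (anyNA(v)) next
    cc <- correlate_scores(model$scores, v)
    corr <- rbind(corr, cbind(weight = wtrait, cc))
  }
  if (!is.null(corr)) {
    utils::write.csv(corr, out("score_weight_correlations.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "rootstress",
    package_version = as.character(utils::packageVersion("rootstress")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stage_seeds = list(permanova = config$seed + 1000L,
                       pairwise = config$seed + 2000L,
                       perf = config$seed + 3000L,
                       tune = config$seed + 4000L),
    alpha = config$alpha, n_permutations = config$n_permutations,
    folds = config$folds, repeats = config$repeats,
    max_ncomp = config$max_ncomp,
    keepX = model$keepX,
    synthetic_seed = if (!is.null(config$synthetic))
      config$synthetic$seed else NULL,
    input = config$input
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  say("done")
  invisible(list(dataset = dataset, screen = screen, interaction = inter,
                 permanova = pv, pairwise = pw, perf = cv, tune = tn,
                 model = model, correlations = corr, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
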