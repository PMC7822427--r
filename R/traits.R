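#' Derive morphological traits from raw root measurements
#'
#' Computes, per root record, the root length ratio and its morphological
#' components: RLR = L / PDW (cm g-1), RMR = DW / PDW (g g-1),
#' fineness RF = L / V (cm cm-3) and tissue density RTD = DW / V (g cm-3).
#' These satisfy the decomposition RLR = RMR x RF / RTD exactly, because
#' (DW/PDW) x (L/V) / (DW/V) = L/PDW. For axis root types (primary, seminal)
#' branching density BD = lateral_count / branching_zone (n cm-1) is added;
#' for lateral root types the lateral count and the average lateral length
#' L / count are reported instead.
#'
#' @param raw Data.frame of raw root records with columns `root_type`,
#'   `length` (cm), `volume` (cm3), `dry_weight` (g) and, depending on root
#'   type, `lateral_count` and `branching_zone`.
#' @param plant_dry_weight Whole-plant dry weight PDW (g), scalar or one per
#'   row of `raw`.
#' @return `raw` with derived columns `rlr`, `rmr`, `fineness`,
#'   `tissue_density` and, where applicable, `branching_density` /
#'   `average_length` appended.
#' @examples
#' r <- data.frame(root_type = "primary", length = 49, volume = 0.14583,
#'                 dry_weight = 0.0111, lateral_count = 208L,
#'                 branching_zone = 42)
#' derive_traits(r, plant_dry_weight = 0.8)
#' @export
derive_traits <- function(raw, plant_dry_weight) {
  stopifnot(is.data.frame(raw),
            all(c("root_type", "length", "volume", "dry_weight") %in%
                  names(raw)))
  pdw <- rep_len(plant_dry_weight, nrow(raw))
  if (any(!is.finite(pdw)) || any(pdw <= 0)) {
    stop("plant dry weight must be positive and finite", call. = FALSE)
  }
  if (any(raw$length <= 0) || any(raw$volume <= 0) || any(raw$dry_weight <= 0)) {
    stop("length, volume and dry weight must be positive", call. = FALSE)
  }
  out <- raw
  out$rlr <- raw$length / pdw
  out$rmr <- raw$dry_weight / pdw
  out$fineness <- raw$length / raw$volume
  out$tissue_density <- raw$dry_weight / raw$volume
  is_axis <- raw$root_type %in% c("primary", "seminal")
  out$branching_density <- NA_real_
  out$average_length <- NA_real_
  if (any(is_axis)) {
    if (!all(c("lateral_count", "branching_zone") %in% names(raw))) {
      stop("axis records need lateral_count and branching_zone", call. = FALSE)
    }
    bz <- raw$branching_zone[is_axis]
    if (any(!is.finite(bz)) || any(bz <= 0)) {
      stop("branching zone must be positive for axis root types",
           call. = FALSE)
    }
    out$branching_density[is_axis] <- raw$lateral_count[is_axis] / bz
  }
  if (any(!is_axis)) {
    if (!"lateral_count" %in% names(raw)) {
      stop("lateral records need lateral_count", call. = FALSE)
    }
    cnt <- raw$lateral_count[!is_axis]
    if (any(cnt <= 0)) {
      stop("lateral count must be positive for lateral root types",
           call. = FALSE)
    }
    out$average_length[!is_axis] <- raw$length[!is_axis] / cnt
  }
  out
}

#' Whole-plant totals from per-root-type records and shoot weights
#'
#' Root fresh/dry weight are sums over the four root types; plant fresh/dry
#' weight add the shoot. Every plant must carry all four root types.
#'
#' @param roots Data.frame of raw root records (`plant_id`, `root_type`,
#'   `fresh_weight`, `dry_weight`).
#' @param shoot_fresh_weight,shoot_dry_weight Per-plant shoot weights (g),
#'   in the order of `unique(roots$plant_id)` or named by plant id.
#' @return Data.frame per plant: `plant_id`, `root_fresh_weight` (RFW),
#'   `root_dry_weight` (RDW), `plant_fresh_weight` (PFW),
#'   `plant_dry_weight` (PDW).
#' @export
plant_totals <- function(roots, shoot_fresh_weight, shoot_dry_weight) {
  stopifnot(is.data.frame(roots),
            all(c("plant_id", "root_type", "fresh_weight", "dry_weight") %in%
                  names(roots)))
  ids <- unique(roots$plant_id)
  for (id in ids) {
    have <- roots$root_type[roots$plant_id == id]
    miss <- setdiff(root_types(), have)
    if (length(miss)) {
      stop("incomplete plant ", id, ": missing root type(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  shfw <- rep_len(shoot_fresh_weight, length(ids))
  shdw <- rep_len(shoot_dry_weight, length(ids))
  if (!is.null(names(shoot_fresh_weight))) shfw <- shoot_fresh_weight[ids]
  if (!is.null(names(shoot_dry_weight))) shdw <- shoot_dry_weight[ids]
  if (any(shfw <= 0) || any(shdw <= 0)) {
    stop("shoot weights must be positive", call. = FALSE)
  }
  rfw <- tapply(roots$fresh_weight, roots$plant_id, sum)[ids]
  rdw <- tapply(roots$dry_weight, roots$plant_id, sum)[ids]
  data.frame(plant_id = ids,
             root_fresh_weight = as.numeric(rfw),
             root_dry_weight = as.numeric(rdw),
             plant_fresh_weight = as.numeric(shfw + rfw),
             plant_dry_weight = as.numeric(shdw + rdw),
             stringsAsFactors = FALSE)
}

#' Tidy per-plant dataset from raw measurements
#'
#' Runs [plant_totals()] and [derive_traits()] over a raw measurement table
#' and emits the tidy trait dialect: one row per plant x root type x trait,
#' covering raw measurements, derived traits and whole-plant totals (the
#' latter under `root_type = "plant"`).
#'
#' @param raw_roots Raw per-root-type records (see [derive_traits()]),
#'   plus `plant_id`, `treatment`, `fresh_weight`, `surface_area`.
#' @param raw_plants Per-plant table with `plant_id`, `treatment`,
#'   `shoot_fresh_weight`, `shoot_dry_weight`.
#' @return Tidy data.frame `plant_id`, `treatment`, `root_type`, `trait`,
#'   `value`.
#' @export
derive_dataset <- function(raw_roots, raw_plants) {
  stopifnot(is.data.frame(raw_plants),
            all(c("plant_id", "treatment", "shoot_fresh_weight",
                  "shoot_dry_weight") %in% names(raw_plants)))
  totals <- plant_totals(
    raw_roots,
    stats::setNames(raw_plants$shoot_fresh_weight, raw_plants$plant_id),
    stats::setNames(raw_plants$shoot_dry_weight, raw_plants$plant_id)
  )
  pdw <- stats::setNames(totals$plant_dry_weight, totals$plant_id)
  der <- derive_traits(raw_roots, pdw[raw_roots$plant_id])
  tidy_cols <- c("length", "surface_area", "volume", "fresh_weight",
                 "dry_weight", "root_zone", "branching_zone",
                 "rlr", "rmr", "fineness", "tissue_density",
                 "branching_density", "average_length")
  rows <- lapply(tidy_cols, function(tr) {
    if (!tr %in% names(der)) return(NULL)
    v <- der[[tr]]
    keep <- is.finite(v)
    if (!any(keep)) return(NULL)
    data.frame(plant_id = der$plant_id[keep], treatment = der$treatment[keep],
               root_type = der$root_type[keep], trait = tr, value = v[keep],
               stringsAsFactors = FALSE)
  })
  cnt <- !der$root_type %in% c("primary", "seminal")
  rows <- c(rows, list(data.frame(
    plant_id = der$plant_id[cnt], treatment = der$treatment[cnt],
    root_type = der$root_type[cnt], trait = "number",
    value = as.numeric(der$lateral_count[cnt]), stringsAsFactors = FALSE)))
  trt <- stats::setNames(raw_plants$treatment, raw_plants$plant_id)
  plant_rows <- do.call(rbind, lapply(
    c("root_fresh_weight", "root_dry_weight",
      "plant_fresh_weight", "plant_dry_weight"),
    function(tr) data.frame(
      plant_id = totals$plant_id, treatment = as.character(trt[totals$plant_id]),
      root_type = "plant", trait = tr, value = totals[[tr]],
      stringsAsFactors = FALSE)
  ))
  out <- rbind(do.call(rbind, rows), plant_rows)
  out <- out[order(match(out$treatment, unique(raw_plants$treatment)),
                   out$plant_id, out$root_type, out$trait), ]
  rownames(out) <- NULL
  class(out) <- c("plant_dataset", class(out))
  out
}
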