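#' One-way ANOVA on a list of groups
#'
#' Classical fixed-effects between/within decomposition with an F test
#' (equal-variance form), as used to screen each root trait across the
#' stress treatments.
#'
#' @param groups List of numeric vectors, one per treatment group (>= 2
#'   groups, each with >= 2 observations).
#' @return List with `F`, `df_between`, `df_within`, `p`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3, df 2,6
#' @export
one_way_anova <- function(groups) {
  .check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  if (stats::var(values) == 0) {
    stop("degenerate data: all values identical", call. = FALSE)
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic),
       df_between = unname(ft$parameter[1L]),
       df_within = unname(ft$parameter[2L]),
       p = unname(ft$p.value))
}

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(lengths(groups) < 2L)) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (any(!vapply(groups, is.numeric, logical(1)))) {
    stop("groups must be numeric vectors", call. = FALSE)
  }
  invisible(groups)
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' All-pairs comparisons with studentized-range p-values (Tukey--Kramer form
#' under unequal group sizes).
#'
#' @param groups List of numeric vectors; names are used as group labels.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Data.frame with one row per pair: `group1`, `group2`, `diff`
#'   (mean2 - mean1), `lwr`, `upr`, `p`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  .check_groups(groups)
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  values <- unlist(groups, use.names = FALSE)
  if (stats::var(values) == 0) {
    stop("degenerate data: all values identical", call. = FALSE)
  }
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("G", seq_along(groups))
  g <- factor(rep(labs, lengths(groups)), levels = labs)
  tk <- stats::TukeyHSD(stats::aov(values ~ g), conf.level = 1 - alpha)$g
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(
    group1 = vapply(pair, `[`, character(1), 2L),
    group2 = vapply(pair, `[`, character(1), 1L),
    diff = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    p = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Compact letter display from a pairwise comparison table
#'
#' Insert-and-absorb letter assignment: groups sharing a letter are not
#' significantly different, groups sharing no letter are. Letters are
#' ordered so that the group with the largest mean carries "a" (the
#' convention of published trait tables). Non-transitive significance
#' patterns are representable (a group may hold several letters).
#'
#' @param pairwise Data.frame as returned by [tukey_hsd()] (columns
#'   `group1`, `group2`, `significant`).
#' @param means Named numeric vector of group means (for letter ordering);
#'   defaults to zero for all groups (alphabetical-insertion order).
#' @return Data.frame `group`, `letters` (comma-separated letter set).
#' @examples
#' pw <- data.frame(group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
#'                  significant = c(FALSE, TRUE, FALSE))
#' compact_letter_display(pw, c(A = 3, B = 2, C = 1))  # a / a,b / b
#' @export
compact_letter_display <- function(pairwise, means = NULL) {
  stopifnot(is.data.frame(pairwise),
            all(c("group1", "group2", "significant") %in% names(pairwise)))
  grps <- unique(c(pairwise$group1, pairwise$group2))
  if (is.null(means)) means <- stats::setNames(numeric(length(grps)), grps)
  grps <- grps[order(-means[grps])]
  # columns = candidate letters, each a membership set; start all-in-one
  cols <- list(grps)
  sig <- pairwise[pairwise$significant, , drop = FALSE]
  if (nrow(sig)) {
    for (r in seq_len(nrow(sig))) {
      a <- sig$group1[r]; b <- sig$group2[r]
      newcols <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          newcols <- c(newcols, list(setdiff(col, a)), list(setdiff(col, b)))
        } else {
          newcols <- c(newcols, list(col))
        }
      }
      # absorb: drop a column contained in another (duplicates keep first)
      keep <- rep(TRUE, length(newcols))
      for (i in seq_along(newcols)) {
        for (j in seq_along(newcols)) {
          if (i == j || !keep[j]) next
          sub_ij <- all(newcols[[i]] %in% newcols[[j]])
          equal <- sub_ij && length(newcols[[i]]) == length(newcols[[j]])
          if (sub_ij && (!equal || j < i)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      cols <- newcols[keep]
    }
  }
  # order letters by the highest-mean member of each column
  first_rank <- vapply(cols, function(col) min(match(col, grps)), numeric(1))
  cols <- cols[order(first_rank)]
  letter <- letters[seq_along(cols)]
  out <- data.frame(group = grps, letters = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    out$letters[i] <- paste(letter[vapply(cols, function(col)
      out$group[i] %in% col, logical(1))], collapse = ",")
  }
  out
}

#' Univariate screen of every trait in a plant dataset
#'
#' Per root type x trait: one-way ANOVA across treatments, Tukey pairwise
#' comparisons and a compact letter display -- the machinery behind a
#' published per-treatment trait table. Degenerate traits (zero within-cell
#' variance everywhere) are flagged, not fatal.
#'
#' @param dataset Tidy `plant_dataset` data.frame with >= 2 treatments.
#' @param alpha Significance level (default 0.05).
#' @param letters Compute Tukey letters (default TRUE); disable for fast
#'   ANOVA-only screening.
#' @return List of class `"trait_screen"`: `$anova` (one row per trait:
#'   `root_type`, `trait`, `F`, `df_between`, `df_within`, `p`,
#'   `significant`, `degenerate`), `$cells` (one row per trait x treatment:
#'   `mean`, `se`, `n`, `letters`, `differs_from_control`), and `$counts`
#'   per root type: traits significant by ANOVA and traits whose letter set
#'   is disjoint from Control's.
#' @export
trait_screen <- function(dataset, alpha = 0.05, letters = TRUE) {
  .check_dataset(dataset)
  trts <- intersect(treatment_levels(), unique(dataset$treatment))
  if (length(trts) < 2L) trts <- unique(dataset$treatment)
  if (length(trts) < 2L) stop("need >= 2 treatments", call. = FALSE)
  combos <- unique(dataset[c("root_type", "trait")])
  anova_rows <- list()
  cell_rows <- list()
  for (i in seq_len(nrow(combos))) {
    rt <- combos$root_type[i]; tr <- combos$trait[i]
    d <- dataset[dataset$root_type == rt & dataset$trait == tr, ]
    groups <- lapply(trts, function(t) d$value[d$treatment == t])
    names(groups) <- trts
    groups <- groups[lengths(groups) >= 2L]
    cells <- data.frame(
      root_type = rt, trait = tr, treatment = names(groups),
      mean = vapply(groups, mean, numeric(1)),
      se = vapply(groups, function(v) stats::sd(v) / sqrt(length(v)),
                  numeric(1)),
      n = lengths(groups), letters = NA_character_,
      row.names = NULL, stringsAsFactors = FALSE
    )
    degenerate <- length(groups) < 2L ||
      stats::var(unlist(groups, use.names = FALSE)) == 0 ||
      sum(vapply(groups, stats::var, numeric(1))) == 0
    if (degenerate) {
      anova_rows[[i]] <- data.frame(
        root_type = rt, trait = tr, F = NA_real_, df_between = NA_real_,
        df_within = NA_real_, p = NA_real_, significant = FALSE,
        degenerate = TRUE, stringsAsFactors = FALSE)
    } else {
      a <- one_way_anova(groups)
      anova_rows[[i]] <- data.frame(
        root_type = rt, trait = tr, F = a$F, df_between = a$df_between,
        df_within = a$df_within, p = a$p, significant = a$p < alpha,
        degenerate = FALSE, stringsAsFactors = FALSE)
      if (letters) {
        cld <- compact_letter_display(
          tukey_hsd(groups, alpha),
          stats::setNames(cells$mean, cells$treatment))
        cells$letters <- cld$letters[match(cells$treatment, cld$group)]
      }
    }
    cell_rows[[i]] <- cells
  }
  anova_tab <- do.call(rbind, anova_rows)
  cells <- do.call(rbind, cell_rows)
  cells$differs_from_control <- NA
  if (letters && "Control" %in% trts) {
    key <- paste(cells$root_type, cells$trait)
    for (k in unique(key)) {
      idx <- key == k
      ctrl <- cells$letters[idx & cells$treatment == "Control"]
      if (length(ctrl) != 1L || is.na(ctrl)) next
      ctrl_set <- strsplit(ctrl, ",", fixed = TRUE)[[1L]]
      cells$differs_from_control[idx] <- vapply(
        cells$letters[idx], function(l) {
          if (is.na(l)) return(NA)
          !any(strsplit(l, ",", fixed = TRUE)[[1L]] %in% ctrl_set)
        }, logical(1))
    }
  }
  counts <- do.call(rbind, lapply(unique(anova_tab$root_type), function(rt) {
    a <- anova_tab[anova_tab$root_type == rt, ]
    cc <- cells[cells$root_type == rt & cells$treatment != "Control", ]
    diff_traits <- unique(cc$trait[cc$differs_from_control %in% TRUE])
    data.frame(root_type = rt,
               n_traits = nrow(a),
               n_significant_anova = sum(a$significant, na.rm = TRUE),
               n_differ_from_control = length(diff_traits),
               stringsAsFactors = FALSE)
  }))
  structure(list(anova = anova_tab, cells = cells, counts = counts,
                 alpha = alpha),
            class = "trait_screen")
}

#' Render a trait screen as a publication-style summary table
#'
#' One row per trait, one "mean (se) letters" column per treatment.
#'
#' @param screen A [trait_screen()] result.
#' @param digits Significant digits for means/SEs (default 4).
#' @return Data.frame with `root_type`, `trait` and one character column per
#'   treatment.
#' @export
format_screen_table <- function(screen, digits = 4) {
  stopifnot(inherits(screen, "trait_screen"))
  cells <- screen$cells
  trts <- intersect(treatment_levels(), unique(cells$treatment))
  combos <- unique(cells[c("root_type", "trait")])
  out <- combos
  for (t in trts) {
    out[[t]] <- vapply(seq_len(nrow(combos)), function(i) {
      r <- cells[cells$root_type == combos$root_type[i] &
                   cells$trait == combos$trait[i] & cells$treatment == t, ]
      if (!nrow(r)) return(NA_character_)
      lab <- if (is.na(r$letters[1L])) "" else paste0(" ", r$letters[1L])
      paste0(signif(r$mean[1L], digits), " (", signif(r$se[1L], digits), ")",
             lab)
    }, character(1))
  }
  rownames(out) <- NULL
  out
}
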