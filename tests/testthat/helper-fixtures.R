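# Planted-signal 4-class data for sPLS-DA recovery checks: three traits
# carry class contrasts with four distinct values each (so one trait per
# component suffices for classification), one trait is pure noise.
planted_splsda_data <- function(seed, n_per_class = 4L, p = 4L,
                                noise = c(0.05, 0.06, 0.07)) {
  set.seed(seed)
  g <- factor(rep(treatment_levels(), each = n_per_class),
              levels = treatment_levels())
  n <- length(g)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("t", seq_len(p))))
  ci <- as.integer(g)
  contrasts <- list(c(-3, -1, 1, 3) / 2,
                    c(1, -3, 3, -1) / 2,
                    c(2, -2, -1, 1) / 1.5)
  for (j in 1:3) {
    X[, j] <- contrasts[[j]][ci] + stats::rnorm(n, sd = noise[j])
  }
  list(X = X, labels = g)
}

# Null specs: every treatment shares the Control cell values, so any
# detected treatment effect is a false positive.
null_specs <- function(root_type_use = "primary") {
  fx <- builtin_table_fixtures()
  fx <- fx[fx$root_type == root_type_use, ]
  ctrl <- fx[fx$treatment == "Control", ]
  do.call(rbind, lapply(treatment_levels(), function(t) {
    s <- ctrl
    s$treatment <- t
    s
  }))
}

# Small raw measurement table with all four root types for n plants.
tiny_raw_plants <- function(n = 2L) {
  ids <- sprintf("P%02d", seq_len(n))
  roots <- expand.grid(plant_id = ids, root_type = root_types(),
                       stringsAsFactors = FALSE)
  m <- nrow(roots)
  roots$treatment <- "Control"
  roots$length <- seq(40, 60, length.out = m)
  roots$surface_area <- seq(8, 12, length.out = m)
  roots$volume <- seq(0.1, 0.3, length.out = m)
  roots$fresh_weight <- seq(0.1, 0.3, length.out = m)
  roots$dry_weight <- seq(0.01, 0.03, length.out = m)
  roots$lateral_count <- rep(100L, m)
  roots$root_zone <- rep(5, m)
  roots$branching_zone <- rep(30, m)
  plants <- data.frame(plant_id = ids, treatment = "Control",
                       shoot_fresh_weight = rep(0.9, n),
                       shoot_dry_weight = rep(0.09, n),
                       stringsAsFactors = FALSE)
  list(roots = roots, plants = plants)
}
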