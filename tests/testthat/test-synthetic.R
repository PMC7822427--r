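test_that("generation is a pure function of the config and seed", {
  cfg <- synthetic_config(seed = 11)
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))
  cfg_raw <- synthetic_config(seed = 11, mode = "raw_level")
  expect_identical(generate_dataset(cfg_raw), generate_dataset(cfg_raw))
  # different seed, different data
  d2 <- generate_dataset(synthetic_config(seed = 12))
  expect_false(identical(generate_dataset(cfg)$value, d2$value))
})

test_that("generated values are positive and zero noise degenerates to the mean", {
  d <- generate_dataset(synthetic_config(seed = 3))
  expect_true(all(d$value > 0))
  specs0 <- builtin_table_fixtures()
  specs0$se <- 0
  d0 <- generate_dataset(synthetic_config(seed = 3, specs = specs0))
  m <- merge(d0, specs0, by = c("root_type", "trait", "treatment"))
  expect_equal(m$value, m$mean)
})

test_that("large-sample moments match the configured law", {
  fx <- builtin_table_fixtures()
  sub <- fx[(fx$root_type == "primary" & fx$trait == "fineness") |
              (fx$root_type == "primary_lateral" & fx$trait == "rlr"), ]
  d <- generate_dataset(synthetic_config(seed = 5, n_per_treatment = 10000,
                                         specs = sub))
  for (i in seq_len(nrow(sub))) {
    v <- d$value[d$root_type == sub$root_type[i] & d$trait == sub$trait[i] &
                   d$treatment == sub$treatment[i]]
    expect_equal(mean(v), sub$mean[i], tolerance = 0.02)
    expect_equal(sd(v), sd_from_se(sub$se[i], sub$n[i]),
                 tolerance = 0.02)
  }
  # the worked check: fineness under drought within 1 percent of 531
  v <- d$value[d$root_type == "primary" & d$trait == "fineness" &
                 d$treatment == "Drought"]
  expect_lt(abs(mean(v) - 531) / 531, 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(), "seed")
  expect_error(synthetic_config(seed = 1, n_per_treatment = 1), ">= 2")
  expect_error(synthetic_config(seed = 1, treatments = c("A", "A")), "unique")
  expect_error(synthetic_config(seed = 1, treatments = c("Control", "Frost")),
               "Frost")
  expect_error(synthetic_config(seed = 1, root_types = "crown"), "crown")
  expect_error(generate_dataset(list(seed = 1)), "synthetic_config")
})

test_that("summaries, wide pivots and CSV io round-trip the tidy dialect", {
  cfg <- synthetic_config(seed = 21)
  d <- generate_dataset(cfg)
  s <- summarize_treatments(d)
  expect_true(all(s$n == 4))
  one <- d$value[d$root_type == "primary" & d$trait == "length" &
                   d$treatment == "Control"]
  expect_equal(s$mean[s$root_type == "primary" & s$trait == "length" &
                        s$treatment == "Control"], mean(one))
  w <- trait_matrix(d)
  expect_equal(nrow(w), 16)
  expect_equal(ncol(w) - 2L, 42)  # 11 + 11 + 10 + 10 trait columns
  expect_true(all(c("plant_id", "treatment") %in% names(w)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(d, path)
  d2 <- read_dataset_csv(path)
  expect_equal(d2$value, d$value)
  expect_equal(d2$plant_id, d$plant_id)
})

test_that("raw-level generation is centred on the configured trait values", {
  d <- generate_dataset(synthetic_config(seed = 9, n_per_treatment = 300,
                                         mode = "raw_level"))
  s <- summarize_treatments(d)
  fx <- builtin_table_fixtures()
  for (row in list(c("primary", "rlr", "Drought"),
                   c("primary_lateral", "fineness", "Combined"),
                   c("seminal", "rmr", "Control"))) {
    got <- s$mean[s$root_type == row[1] & s$trait == row[2] &
                    s$treatment == row[3]]
    want <- fx$mean[fx$root_type == row[1] & fx$trait == row[2] &
                      fx$treatment == row[3]]
    expect_equal(got, want, tolerance = 0.1)
  }
})
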