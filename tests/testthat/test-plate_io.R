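# a small 3-well plate built in code: 97 time points at 10-min spacing
make_fixture <- function(n_wells = 3, n_times = 97) {
  tt <- seq(0, by = 1 / 6, length.out = n_times)
  do.call(rbind, lapply(seq_len(n_wells), function(w) {
    data.frame(well = paste0("A", w), condition = "ctrl", channel = "OD600",
               time_hr = tt, value = 0.05 + 0.4 / (1 + exp(-(tt - 6))) +
                 0.001 * w)
  }))
}

test_that("long-form plate CSVs round-trip and validate their grid", {
  ds <- plate_dataset(make_fixture())
  expect_equal(attr(ds, "interval"), 1 / 6, tolerance = 1e-12)
  expect_equal(length(unique(ds$well)), 3)

  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(ds, path)
  back <- read_plate_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(ds), tolerance = 1e-12)

  # a missing time point in one well is a format error
  broken <- make_fixture()
  broken <- broken[-5, ]
  expect_error(plate_dataset(broken), "missing time points")

  dup <- rbind(make_fixture(), make_fixture()[1, ])
  expect_error(plate_dataset(dup), "duplicate")

  ragged <- make_fixture()
  ragged$time_hr[3] <- ragged$time_hr[2]
  expect_error(plate_dataset(ragged), "duplicate|uniform")
})

test_that("wide-form exports are reshaped through a layout map", {
  tt <- seq(0, by = 1 / 6, length.out = 20)
  wide <- data.frame(time_hr = tt, A1 = tt + 1, A2 = tt + 2, B1 = tt + 3)
  wpath <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(wide, wpath, row.names = FALSE)
  layout <- data.frame(well = c("A1", "A2"), condition = "ctrl")
  expect_warning(ds <- read_plate_csv(wpath, format = "wide",
                                      channel = "OD600", layout = layout),
                 "unmapped")
  expect_equal(sort(unique(ds$well)), c("A1", "A2"))
  expect_equal(ds$value[ds$well == "A2"][1], 2)
  expect_error(read_plate_csv(wpath, format = "wide"), "layout")
})

test_that("path-length correction rescales OD only and composes multiplicatively", {
  fix <- make_fixture(1)
  fl <- fix; fl$channel <- "FL"; fl$value <- 100 + fix$time_hr
  ds <- plate_dataset(rbind(fix, fl))

  c1 <- correct_od(ds, 2.39)
  expect_equal(c1$value[c1$channel == "OD600"],
               2.39 * ds$value[ds$channel == "OD600"])
  expect_equal(c1$value[c1$channel == "FL"], ds$value[ds$channel == "FL"])
  expect_equal(attr(c1, "pathlength_factor"), 2.39)
  expect_equal(correct_od(ds, 1.0)$value, ds$value)

  # applying a then b equals applying a*b once
  ab <- correct_od(correct_od(ds, 1.7), 2.0)
  once <- correct_od(ds, 3.4)
  expect_equal(ab$value, once$value, tolerance = 1e-12)
  expect_error(correct_od(ds, -2), "> 0")

  # raw OD 0.1 under the calibrated default
  raw <- plate_dataset(data.frame(well = "w", condition = "c",
                                  channel = "OD600", time_hr = c(0, 1 / 6),
                                  value = c(0.1, 0.1)))
  expect_equal(correct_od(raw)$value, c(0.239, 0.239))
})

test_that("replicate aggregation computes mean and SEM as defined", {
  tt <- c(0, 1 / 6)
  df <- do.call(rbind, lapply(1:3, function(w) {
    data.frame(well = paste0("r", w), condition = "ctrl", channel = "OD600",
               time_hr = tt, value = c(w, 0.1))
  }))
  cc <- aggregate_condition(plate_dataset(df), "ctrl")
  expect_equal(cc$mean[1], 2)               # mean of 1, 2, 3
  expect_equal(cc$sem[1], 1 / sqrt(3))      # SD = 1
  expect_equal(cc$mean[2], 0.1)
  expect_equal(cc$sem[2], 0)
  expect_equal(cc$n_replicates, 3)
  expect_false(cc$single_replicate)

  single <- aggregate_condition(plate_dataset(df[df$well == "r1", ]), "ctrl")
  expect_true(single$single_replicate)
  expect_equal(single$sem, c(0, 0))
  expect_error(aggregate_condition(plate_dataset(df), "nope"), "no wells")
})

test_that("aggregation commutes with path-length correction", {
  sp <- generate_plate_dataset(n_replicates = 3,
                               meas = measurement_model(seed = 4))
  a <- aggregate_condition(correct_od(sp$dataset), "control")
  b <- aggregate_condition(sp$dataset, "control")
  expect_equal(a$mean, 2.39 * b$mean, tolerance = 1e-12)
  expect_equal(a$sem, 2.39 * b$sem, tolerance = 1e-12)
})

test_that("SEM shrinks like 1/sqrt(n) on resampled replicate subsets", {
  sp <- generate_plate_dataset(n_replicates = 12, interval = 0.5,
                               meas = measurement_model(seed = 9,
                                                        noise_cv = 0.05))
  ds <- sp$dataset
  sem_n <- vapply(c(3, 12), function(n) {
    keep <- ds$well %in% sprintf("control_r%d", 1:n)
    mean(aggregate_condition(plate_dataset(ds[keep, ]), "control")$sem)
  }, numeric(1))
  # quadrupling the replicates should roughly halve the SEM
  expect_equal(sem_n[1] / sem_n[2], 2, tolerance = 0.5)
})

test_that("condition analysis recovers known shifts and flags flat blanks", {
  mA <- measurement_model(seed = 21)
  mB <- measurement_model(seed = 22)
  a <- generate_plate_dataset(growth_params(alpha = 1), meas = mA,
                              condition = "ctrl")
  b <- generate_plate_dataset(growth_params(alpha = 0.1), meas = mB,
                              condition = "treated")
  truth_shift <- b$truth$tau_p - a$truth$tau_p
  an_a <- analyze_condition(aggregate_condition(correct_od(a$dataset), "ctrl"))
  an_b <- analyze_condition(aggregate_condition(correct_od(b$dataset),
                                                "treated"))
  got <- peak_shift(an_a$peak, an_b$peak)
  expect_equal(got$shift, truth_shift, tolerance = 0.5 + 1e-9)
  expect_s3_class(an_a$gompertz, "gompertz_fit")

  # flat blank well: degenerate peak, labelled with the condition
  blank <- data.frame(well = "b1", condition = "blank", channel = "OD600",
                      time_hr = seq(0, 16, 1 / 6), value = 0.04)
  cc <- aggregate_condition(plate_dataset(blank), "blank")
  expect_error(analyze_condition(cc), "blank")
})

test_that("the FL second-derivative peak lags the OD first-derivative peak", {
  sp <- generate_plate_dataset(meas = measurement_model(seed = 30))
  ds <- correct_od(sp$dataset)
  od <- analyze_condition(aggregate_condition(ds, "control", "OD600"))
  fl <- analyze_condition(aggregate_condition(ds, "control", "FL"),
                          smooth_window = 15, resmooth = TRUE)
  expect_gt(fl$peak$tau, od$peak$tau)
  expect_equal(fl$peak$tau - od$peak$tau, sp$truth$tau_pf - sp$truth$tau_p,
               tolerance = 1)
})
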