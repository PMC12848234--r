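test_that("write/read round trip preserves values and row order", {
  tab <- sim_measurement_table(4, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_site_table(tab, path)
  back <- read_site_table(path)
  expect_s3_class(back, "site_table")
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$site_id, tab$site_id)
  for (col in setdiff(names(tab), c("site_id", "species")))
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-9)
})

test_that("schema errors are informative", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,t_meas", "a,25"), path)
  expect_error(read_site_table(path), "vcmax_tmeas")
  writeLines(c("site_id,vcmax_tmeas,t_meas", "a,oops,25"), path)
  expect_error(read_site_table(path), "vcmax_tmeas.*row 1|row 1")
})

test_that("schema_config maps columns and declares sentinels", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,myVcmax,Tleaf,ph", "a,50,25,-9999", "b,60,30,6.5"), path)
  cfg <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ID = site_id", "myVcmax = vcmax_tmeas", "Tleaf = t_meas",
               "ph = soil_ph", "na_sentinel = -9999"), cfg)
  tab <- read_site_table(path, cfg)
  expect_equal(tab$vcmax_tmeas, c(50, 60))
  expect_true(is.na(tab$soil_ph[1]))
  expect_equal(tab$soil_ph[2], 6.5)
})

test_that("concurrent-measurement filter keeps the right records untouched", {
  tab <- sim_measurement_table(5, seed = 2, measurements_per_site = 1)
  tab$t_meas[c(2, 4)] <- NA
  out <- filter_concurrent(tab)
  expect_equal(nrow(out), 3)
  rep <- attr(out, "filter_report")
  expect_equal(rep$records_kept, 3)
  kept_ids <- out$site_id
  for (col in c("vcmax_tmeas", "t_g", "soil_ph", "na"))
    expect_identical(out[[col]], tab[[col]][tab$site_id %in% kept_ids])
  # missing trait column empties the table with a warning, not an error
  tab$na <- NA_real_
  expect_warning(res <- filter_concurrent(tab, require_traits = TRUE),
                 "no records")
  expect_equal(nrow(res), 0)
})

test_that("filter counts match brute-force expectation under known missingness", {
  tab <- sim_measurement_table(50, seed = 9, measurements_per_site = 2)
  rs <- withr::with_seed(11, sample(nrow(tab), 30))
  tab$t_meas[rs] <- NA
  expected <- sum(!is.na(tab$t_meas) & !is.na(tab$vcmax_tmeas))
  expect_equal(nrow(filter_concurrent(tab)), expected)
})

test_that("site-mean aggregation averages, is idempotent, and flags level", {
  tab <- sim_measurement_table(3, seed = 5, measurements_per_site = 1)
  tab2 <- rbind(as.data.frame(tab), as.data.frame(tab)[1, ])
  tab2$vcmax_tmeas[c(1, 4)] <- c(40, 60)
  tab2 <- structure(tab2, class = c("site_table", "data.frame"),
                    level = "measurement")
  agg <- aggregate_site_means(tab2)
  expect_equal(attr(agg, "level"), "site-mean")
  expect_equal(nrow(agg), 3)
  expect_equal(agg$vcmax_tmeas[agg$site_id == tab$site_id[1]], 50)
  # single-measurement sites unchanged
  expect_equal(agg$vcmax_tmeas[agg$site_id == tab$site_id[2]],
               tab$vcmax_tmeas[2])
  expect_equal(as.data.frame(aggregate_site_means(agg)), as.data.frame(agg))
})

test_that("site means converge to generator means with many replicates", {
  sim <- generate_sites(generator_config(n_sites = 5, measurements_per_site = 100,
                                         meas_noise_sd = 0.05), seed = 21)
  agg <- aggregate_site_means(sim$table)
  obs25 <- observed_vcmax(agg)$vcmax25
  expect_equal(obs25, sim$truth$true_vcmax25, tolerance = 0.05)
})
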