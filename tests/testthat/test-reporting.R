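test_that("the demo configuration loads with every tier resolved", {
  net <- load_network_config(demo_config_path())
  expect_s3_class(net, "network_config")
  expect_length(net$sites, 2)
  expect_equal(net$lab_profile$kit$tests_per_kit, 12L)
  expect_equal(net$lab_profile$kit$kit_price, 875)
  expect_equal(net$lab_profile$kit$controls_per_run, 2L)
  expect_s3_class(net$sites[[1]]$patient, "catchment")
  expect_s3_class(net$sites[[2]]$patient, "patient_aggregate")
  expect_s3_class(net$sites[[1]]$scs$transport, "shipment_profile")
  expect_equal(net$provenance$md5,
               unname(tools::md5sum(demo_config_path())))
})

test_that("schema violations name the offending field", {
  base <- yaml::read_yaml(demo_config_path())

  bad <- base
  bad$sites[[1]]$delivery$fraction_to_scs <- 1.2
  p <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, p)
  err <- expect_error(load_network_config(p), class = "vlcost_schema_error")
  expect_match(conditionMessage(err), "delivery")

  bad2 <- base
  bad2$laboratory <- bad2$lab # unknown top-level key
  p2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad2, p2)
  err2 <- expect_error(load_network_config(p2), class = "vlcost_schema_error")
  expect_match(conditionMessage(err2), "laboratory")

  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_error(load_network_config(empty), class = "vlcost_schema_error")

  expect_error(load_network_config(tempfile(fileext = ".yaml")),
               class = "vlcost_io_error")
})

test_that("network configurations survive a YAML round trip", {
  for (net in list(reference_network(),
                   generate_network(generator_config(seed = 8, n_sites = 2,
                                                     patients_per_site = 25)))) {
    p <- withr::local_tempfile(fileext = ".yaml")
    write_network_config(net, p)
    back <- load_network_config(p)
    expect_equal(tier_share_report(back), tier_share_report(net))
    expect_equal(back$thresholds, net$thresholds)
  }
})

test_that("tier shares are computed before rounding and sum to 100", {
  report <- tier_share_report(reference_network())
  sums <- report$patient_share + report$clinic_share + report$laboratory_share
  expect_true(all(abs(sums - 100) <= 0.2))
  # shares use unrounded tiers over the unrounded total: site 1's clinic
  # share is 6.6 only because 6.578 / 99.006 rounds there
  expect_equal(report$clinic_share[1], 6.6)
})

test_that("emitted tables re-parse to the in-memory report", {
  net <- reference_network()
  out <- withr::local_tempdir()
  paths <- emit_report_tables(net, out)
  expect_true(all(file.exists(paths)))

  t1 <- read.csv(file.path(out, "table1.csv"))
  report <- tier_share_report(net)
  expect_equal(t1$total, report$total)
  expect_equal(t1$patient_share, report$patient_share)
  expect_equal(t1$laboratory, report$laboratory)

  t4 <- read.csv(file.path(out, "table4.csv"))
  expect_equal(t4$batch_10[t4$category == "total cost per specimen"], 97.15)
  expect_equal(t4$batch_22[t4$category == "reagents"], 79.55)

  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$n_sites, 6L)
  expect_equal(manifest$package, "vlcost")
})

test_that("re-running the pipeline produces byte-identical outputs", {
  net <- generate_network(generator_config(seed = 12, n_sites = 2,
                                           patients_per_site = 20))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_report_tables(net, d1)
  emit_report_tables(net, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
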