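test_that("filter boundaries are strict exclusions: threshold values pass", {
  th <- filter_thresholds()
  below <- make_records(1, pct_identity = 89.9)
  res <- apply_assignment_filters(below, th)
  expect_equal(nrow(res$retained), 0L)
  expect_equal(unname(res$audit["identity"]), 1L)

  at <- make_records(1, pct_identity = 90.0, align_len_bp = 100,
                     bit_score = 100)
  expect_equal(nrow(apply_assignment_filters(at, th)$retained), 1L)

  empty <- apply_assignment_filters(make_records(0), th)
  expect_equal(nrow(empty$retained), 0L)
  expect_true(all(empty$audit == 0L))
})

test_that("each criterion excludes independently and the audit attributes all", {
  th <- filter_thresholds()
  cases <- list(
    identity = make_records(1, pct_identity = 80),
    alignment = make_records(1, align_len_bp = 99),
    bitscore = make_records(1, bit_score = 99.9),
    rank = make_records(1, family = ""),
    non_eukaryote = make_records(1, superkingdom = "Bacteria"),
    environmental = make_records(1, env_sample = TRUE))
  for (nm in names(cases)) {
    res <- apply_assignment_filters(cases[[nm]], th)
    expect_equal(nrow(res$retained), 0L, label = nm)
    expect_equal(unname(res$audit[nm]), 1L, label = nm)
  }
  # a record with family empty but genus filled is assigned below family: keep
  gen <- make_records(1, family = "", genus = "Baetis")
  expect_equal(nrow(apply_assignment_filters(gen, th)$retained), 1L)
  # blocklist applies after filtering
  bos <- make_records(2, family = c("Bovidae", "Baetidae"))
  res <- apply_assignment_filters(bos, th, blocklist = "Bovidae")
  expect_identical(res$retained$family, "Baetidae")
  expect_equal(unname(res$audit["blocklist"]), 1L)
})

test_that("audit conservation and threshold monotonicity hold on random tables", {
  for (seed in 1:3) {
    rec <- random_records(300, seed)
    res <- apply_assignment_filters(rec, filter_thresholds())
    expect_equal(unname(res$audit["n_retained"] + res$audit["n_excluded"]),
                 nrow(rec))
    # every dropped record fails at least one criterion
    crit <- res$audit[c("identity", "alignment", "bitscore", "rank",
                        "non_eukaryote", "environmental")]
    expect_gte(sum(crit), unname(res$audit["n_excluded"]))

    base_ids <- res$retained$sequence_id
    for (tweak in list(filter_thresholds(min_identity = 95),
                       filter_thresholds(min_alignment = 150),
                       filter_thresholds(min_bitscore = 400))) {
      ids <- apply_assignment_filters(rec, tweak)$retained$sequence_id
      expect_true(all(ids %in% base_ids))
    }
  }
  bad <- make_records(1); bad$pct_identity <- NA_real_
  expect_error(apply_assignment_filters(bad, filter_thresholds()), "s0001")
})

test_that("geographic verification applies the CH-or-all-four rule", {
  cl <- read_checklist_csv(system.file("extdata", "checklist_synthetic.csv",
                                       package = "ednariver"))
  res <- geographic_verify(c("Baetidae",               # CH
                             "Leuctridae",             # all four neighbours
                             "Culicoides fascipennis", # all four but excluded
                             "Molannidae",             # three neighbours only
                             "Unknownidae"), cl)       # not in checklist
  expect_setequal(res$retained, c("Baetidae", "Leuctridae"))
  expect_equal(res$dropped$reason[res$dropped$taxon == "Culicoides fascipennis"],
               "excluded")
  expect_equal(res$dropped$reason[res$dropped$taxon == "Unknownidae"],
               "unverifiable")
  # order invariance
  res2 <- geographic_verify(rev(c("Baetidae", "Leuctridae", "Molannidae")), cl)
  expect_setequal(res2$retained, c("Baetidae", "Leuctridae"))
})

test_that("mock metrics equal hand counts on a 10-record fixture", {
  rec <- make_records(10, family = c(rep("Baetidae", 6), rep("Perlidae", 3),
                                     "Tabanidae"))
  m <- mock_metrics(rec, truth = c("Baetidae", "Perlidae", "Gammaridae"))
  expect_equal(m$n_sequences, 10L)
  expect_equal(m$pct_sequences_correct, 90)
  expect_equal(m$pct_sequences_incorrect, 10)
  expect_equal(m$n_taxa_detected, 2L)
  expect_equal(m$n_false_positive_taxa, 1L)
  expect_equal(m$taxon_false_positive_rate, 50)
  expect_identical(m$false_positive_taxa, "Tabanidae")

  all_in <- mock_metrics(make_records(5), truth = "Baetidae")
  expect_equal(all_in$pct_sequences_correct, 100)
  expect_equal(all_in$taxon_false_positive_rate, 0)
  expect_error(mock_metrics(rec, character(0)), "empty")
})

test_that("threshold sweep trades false positives for false absences monotonically", {
  fx <- generate_mock_fixture(seed = 7)
  sw <- threshold_sweep(fx$records, fx$truth, identity_grid = c(90, 91, 92, 95, 99))
  expect_true(all(diff(sw$false_absence_rate) >= 0))
  expect_true(all(diff(sw$fp_rate) <= 0))
  # at the base threshold the sweep reproduces base filtering
  expect_equal(sw$n_retained_sequences[1], 57641)
  # an impossible threshold loses every taxon
  sw100 <- threshold_sweep(fx$records, fx$truth, identity_grid = 100)
  expect_equal(sw100$false_absence_rate, 100)
})

test_that("method overlap partitions the detected taxon union", {
  m1 <- rbind(s1 = c(1, 1, 0, 0)); colnames(m1) <- paste0("t", 1:4)
  m2 <- rbind(s1 = c(0, 1, 1, 0)); colnames(m2) <- paste0("t", 1:4)
  ov <- method_overlap(m1, m2)
  expect_equal(ov, list(n_both = 1L, n_edna_only = 1L, n_kicknet_only = 1L,
                        n_total = 3L))
  expect_equal(method_overlap(m1, m1)$n_edna_only, 0L)
  m3 <- rbind(s1 = c(0, 0, 1, 1)); colnames(m3) <- paste0("t", 1:4)
  expect_equal(method_overlap(m1, m3)$n_both, 0L)
})

test_that("habitat partition sums to 100 per phylum and errors on bad labels", {
  df <- data.frame(species = paste0("sp", 1:4), phylum = "Arthropoda",
                   habitat = c("terrestrial", rep("freshwater", 3)))
  hp <- habitat_partition(df)
  expect_equal(hp$pct_terrestrial, 25)
  expect_equal(hp$pct_freshwater, 75)

  allfw <- habitat_partition(data.frame(species = "x", phylum = "Rotifera",
                                        habitat = "freshwater"))
  expect_equal(allfw$pct_terrestrial, 0)

  df$habitat[2] <- "swamp"
  expect_error(habitat_partition(df), "sp2")

  pkg <- glatt_species_synthetic()
  hp2 <- habitat_partition(pkg)
  expect_equal(sum(hp2$n_species), 255L)
  expect_true(all(abs(hp2$pct_terrestrial + hp2$pct_freshwater - 100) < 1e-9))
})

test_that("assignment TSV round-trips through the reader", {
  rec <- random_records(25, seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(rec, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_assignments_tsv(f)
  expect_equal(back$pct_identity, rec$pct_identity)
  expect_equal(back$family, rec$family)
  expect_identical(back$env_sample, rec$env_sample)
})
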