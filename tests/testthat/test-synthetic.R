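cfg <- pipeline_config()

test_that("planted consensus members are recovered exactly", {
  planted <- stats::setNames(c(5L, 5L, 5L, 4L, 4L, 4L, 3L, 3L, 2L, 1L),
                             sprintf("P%02d", 1:10))
  de <- gen_de_tables(5, 120, planted, cfg, seed = 17L)
  sets <- lapply(de, filter_unfiltered_significant, alpha = cfg$alpha)
  # each planted gene is significant in exactly its support-count datasets
  support <- table(unlist(lapply(sets, intersect, names(planted))))
  counts <- as.integer(support[names(planted)])
  counts[is.na(counts)] <- 0L
  expect_equal(counts, as.integer(planted))
  got4 <- k_of_n_consensus(sets, 4)
  expect_setequal(intersect(got4, names(planted)), sprintf("P%02d", 1:6))
  # background genes never reach k datasets
  bg <- setdiff(unlist(sets), names(planted))
  expect_length(intersect(k_of_n_consensus(sets, cfg$consensus_k), bg), 0L)
  got5 <- k_of_n_consensus(sets, 5)
  expect_setequal(intersect(got5, names(planted)), sprintf("P%02d", 1:3))
  expect_error(gen_de_tables(5, 20, c(g = 6L), cfg), "exceeds")
})

test_that("generators are pure functions of spec and seed", {
  planted <- stats::setNames(c(5L, 3L), c("A", "B"))
  expect_identical(gen_de_tables(5, 30, planted, cfg, seed = 4L),
                   gen_de_tables(5, 30, planted, cfg, seed = 4L))
  expect_identical(gen_architecture_specs(25, seed = 8L),
                   gen_architecture_specs(25, seed = 8L))
  sp <- gen_dynamics_specs(25, seed = 8L)
  expect_identical(sp, gen_dynamics_specs(25, seed = 8L))
  expect_identical(gen_timecourse(sp, cfg, seed = 9L),
                   gen_timecourse(sp, cfg, seed = 9L))
  a <- synthetic_anchors(gen_architecture_specs(10, 2L)$gene_id)
  expect_equal(as.data.frame(gen_peakscape(a, gen_architecture_specs(10, 2L),
                                           cfg, seed = 5L)),
               as.data.frame(gen_peakscape(a, gen_architecture_specs(10, 2L),
                                           cfg, seed = 5L)))
})

test_that("planted enhancer architectures are recovered at zero noise", {
  specs <- gen_architecture_specs(120, seed = 31L)
  anchors <- synthetic_anchors(specs$gene_id)
  peaks <- gen_peakscape(anchors, specs, cfg, seed = 32L)
  calls <- profile_genes(anchors, peaks, cfg)
  m <- merge(calls, specs, by = "gene_id")
  expect_equal(m$kind.x, m$kind.y)
  arch <- m$kind.y != "none"
  expect_equal(m$constellation.x[arch], m$constellation.y[arch])
  expect_equal(m$enhancer_ligand_dependent[arch], m$ligand_dependent[arch])
  expect_equal(m$distance_kb.x[arch], m$distance_kb.y[arch])
  expect_equal(m$tss_ligand_dependent.x, m$tss_ligand_dependent.y)
})

test_that("planted response dynamics are recovered at zero noise", {
  specs <- gen_dynamics_specs(120, seed = 41L)
  tc <- gen_timecourse(specs, cfg, seed = 42L)
  tx <- classify_transcriptome(tc, cfg)
  m <- merge(tx, specs, by = "gene_id")
  expect_equal(m$transcriptome_group, m$group)
  expect_equal(m$primary_target, m$primary)
})

test_that("recovery degrades no better than monotonically with noise", {
  specs <- gen_dynamics_specs(150, seed = 51L)
  acc <- vapply(c(0, 0.2, 0.8), function(sd) {
    sp <- specs
    sp$noise_sd <- sd
    tc <- gen_timecourse(sp, cfg, seed = 52L)
    tx <- classify_transcriptome(tc, cfg)
    m <- merge(tx, sp, by = "gene_id")
    mean(m$transcriptome_group == m$group)
  }, numeric(1))
  expect_equal(acc[1], 1)
  expect_gte(acc[1], acc[2])
  expect_gte(acc[2], acc[3] - 0.05)
})

test_that("contradictory specifications are rejected", {
  bad <- data.frame(gene_id = "X", kind = "single", constellation = "T",
                    ligand_dependent = TRUE, tss_ligand_dependent = FALSE,
                    distance_kb = 0, stringsAsFactors = FALSE)
  expect_error(gen_peakscape(synthetic_anchors("X"), bad, cfg, 1L),
               "contradictory")
  bad2 <- data.frame(gene_id = "Y", kind = "super", constellation = "24-24-24",
                     ligand_dependent = FALSE, tss_ligand_dependent = FALSE,
                     distance_kb = 30, stringsAsFactors = FALSE)
  expect_error(gen_peakscape(synthetic_anchors("Y"), bad2, cfg, 1L),
               "persistent or transient")
  small <- gen_dynamics_specs(1, seed = 1L)
  small$group <- 1L
  small$fc24 <- 1.5
  small$primary <- TRUE
  expect_error(gen_timecourse(small, cfg, 1L), "contradictory")
  expect_error(gen_peakscape(synthetic_anchors("A"),
                             gen_architecture_specs(2, 1L), cfg, 1L),
               "unknown anchors")
})

test_that("simulate_inputs writes a loadable, deterministic input set", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- simulate_inputs(d1, n_genes = 60L, n_arch = 8L, n_dyn = 8L,
                        cfg = cfg, seed = 99L)
  simulate_inputs(d2, n_genes = 60L, n_arch = 8L, n_dyn = 8L,
                  cfg = cfg, seed = 99L)
  for (f in list.files(d1))
    expect_equal(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                 info = f)
  de <- read_de_table(p1$de_DS1, "DS1")
  expect_gt(nrow(de), 0L)
  anchors <- read_tss(p1$tss)
  peaks <- read_peaks(p1$peaks)
  calls <- profile_genes(anchors, peaks, cfg)
  truth <- jsonlite::read_json(p1$truth, simplifyVector = TRUE)
  m <- merge(calls, truth$architecture, by = "gene_id")
  expect_equal(m$kind.x, m$kind.y)
  tc <- read_timecourse(p1$timecourse)
  expect_equal(nrow(tc), 8L)
})
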