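cfg <- pipeline_config()

test_that("window queries match a brute-force overlap scan", {
  set.seed(21)
  df <- pk(sample(c("chr1", "chr2"), 1000, replace = TRUE),
           start <- round(runif(1000, 0, 4e6)), start + sample(50:5000, 1000,
           replace = TRUE), name = sprintf("r%04d", 1:1000))
  peaks <- as_peaks(df)
  for (i in 1:10) {
    tss <- round(runif(1, 5e5, 3.5e6))
    r <- sample(c(1e4, 1e5, 1e6), 1)
    a <- anchor1(tss = tss)
    got <- query_window(peaks, a, r)
    want <- oracle_window(df, "chr1", tss, r)
    expect_setequal(S4Vectors::mcols(got)$name, want$name)
  }
  # peak entirely beyond the window edge is excluded
  a <- anchor1(tss = 1000000L)
  edge <- as_peaks(pk("chr1", c(1000000 + 500, 1000000 + 2000),
                      c(1000000 + 600, 1000000 + 2100), name = c("in", "out")))
  got <- query_window(edge, a, 1000L)
  expect_equal(S4Vectors::mcols(got)$name, "in")
  # unknown chromosome warns and returns empty
  expect_warning(out <- query_window(edge, anchor1(chrom = "chrZ"), 1000L),
                 "absent")
  expect_equal(length(out), 0L)
})

test_that("strength assignment honors labels and fills by score quantile", {
  labeled <- as_peaks(pk("chr1", c(100, 300), c(200, 400),
                         site_class = c("P", "T"),
                         strength = c("weak", "strong")))
  out <- assign_strength(labeled, 0.75)
  expect_equal(S4Vectors::mcols(out)$strength, c("weak", "strong"))

  un <- pk("chr1", seq(100, 700, by = 200), seq(200, 800, by = 200),
           site_class = "T", score = 1:4)
  out2 <- assign_strength(as_peaks(un), 0.75)
  m <- S4Vectors::mcols(out2)
  expect_equal(m$strength[order(m$score)], c("weak", "weak", "weak", "strong"))

  single <- assign_strength(as_peaks(pk("chr1", 100, 200, site_class = "P",
                                        score = 5)), 0.75)
  expect_equal(S4Vectors::mcols(single)$strength, "strong")
})

test_that("H3K27ac continuity requires gap-tolerant coverage of the span", {
  span <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 20000))
  cover <- as_peaks(pk("chr1", 500, 25000, assay = "H3K27ac"))
  expect_true(h3k27ac_continuity(span, cover, 1000))
  gap5k <- as_peaks(pk("chr1", c(500, 15000), c(10000, 25000),
                       assay = "H3K27ac"))
  expect_false(h3k27ac_continuity(span, gap5k, 1000))
  expect_true(h3k27ac_continuity(span, gap5k, 5000))
  expect_false(h3k27ac_continuity(span, as_peaks(pk("chr1", integer(0),
                                                    integer(0),
                                                    assay = "H3K27ac")), 1000))
  # random landscapes agree with the independent merge oracle
  set.seed(33)
  for (i in 1:50) {
    nk <- sample(1:6, 1)
    ks <- round(runif(nk, 0, 30000)); kw <- round(runif(nk, 500, 12000))
    k27 <- pk("chr1", ks, ks + kw, assay = "H3K27ac")
    s <- round(runif(1, 0, 15000)); e <- s + round(runif(1, 1000, 15000))
    sp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s + 1, e))
    expect_equal(h3k27ac_continuity(sp, as_peaks(k27), 1000),
                 oracle_continuity(k27$start, k27$end, s, e, 1000))
  }
})

test_that("super-enhancer calls follow the stitching rule", {
  a <- anchor1(tss = 0L)
  mk_vdr <- function(centers, classes, strengths)
    as_peaks(pk("chr1", centers - 100, centers + 100, site_class = classes,
                strength = strengths, name = sprintf("v%d",
                seq_along(centers))))
  blanket <- as_peaks(pk("chr1", -2000, 30000, assay = "H3K27ac"))
  # sites within 20 kb, one strong T, continuous H3K27ac: qualifies
  se <- call_super_enhancer(mk_vdr(c(0, 8000, 18000), c("T", "T", "24"),
                                   c("strong", "weak", "weak")),
                            blanket, a, cfg)
  expect_s3_class(se, "stitched_cluster")
  expect_equal(length(se$sites), 3L)
  # extent over 20 kb: no call
  expect_null(call_super_enhancer(mk_vdr(c(0, 12000, 25000),
                                         c("T", "T", "24"),
                                         c("strong", "weak", "weak")),
                                  blanket, a, cfg))
  # no strong persistent/transient member: no call
  expect_null(call_super_enhancer(mk_vdr(c(0, 8000, 18000),
                                         c("24", "24", "24"),
                                         c("strong", "weak", "weak")),
                                  blanket, a, cfg))
  expect_null(call_super_enhancer(mk_vdr(c(0, 8000, 18000),
                                         c("T", "T", "24"),
                                         c("weak", "weak", "weak")),
                                  blanket, a, cfg))
  # broken H3K27ac: no call
  broken <- as_peaks(pk("chr1", c(-2000, 12000), c(4000, 30000),
                        assay = "H3K27ac"))
  expect_null(call_super_enhancer(mk_vdr(c(0, 8000, 18000),
                                         c("T", "T", "24"),
                                         c("strong", "weak", "weak")),
                                  broken, a, cfg))
})

test_that("super-enhancer calling matches exhaustive subset enumeration", {
  set.seed(55)
  tss <- 2000000L
  a <- anchor1(chrom = "chrR", tss = tss)
  n_checked <- 0L
  for (i in 1:120) {
    land <- random_landscape(tss)
    got <- call_super_enhancer(assign_strength(as_peaks(land$vdr), 0.75),
                               as_peaks(land$k27), a, cfg)
    want <- oracle_super(land$vdr, land$k27, tss)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(GenomicRanges::start(got$span) - 1L, want$start)
      expect_equal(GenomicRanges::end(got$span), want$end)
      expect_equal(length(got$sites), want$size)
    }
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 100L)
})

test_that("single-enhancer fallback picks the closest strong P/T site", {
  a <- anchor1(tss = 100000L)
  vdr <- as_peaks(pk("chr1",
                     100000 + c(-3000, 10000, -500, 2000) - 100,
                     100000 + c(-3000, 10000, -500, 2000) + 100,
                     site_class = c("T", "P", "24", "T"),
                     strength = c("strong", "strong", "strong", "weak"),
                     name = c("t3k", "p10k", "c24", "tweak")))
  sel <- select_single_enhancer(vdr, a)
  expect_equal(S4Vectors::mcols(sel)$name, "t3k")
  # only weak and 24-only sites: none
  none <- as_peaks(pk("chr1", c(1000, 5000), c(1200, 5200),
                      site_class = c("24", "T"),
                      strength = c("strong", "weak")))
  expect_null(select_single_enhancer(none, a))
  # equidistant tie resolves upstream
  tie <- as_peaks(pk("chr1", 100000 + c(-5000, 5000) - 100,
                     100000 + c(-5000, 5000) + 100,
                     site_class = c("T", "T"),
                     strength = c("strong", "strong"),
                     name = c("up", "down")))
  expect_equal(S4Vectors::mcols(select_single_enhancer(tie, a))$name, "up")
})

test_that("constellation labels order classes P < T < 24", {
  mk <- function(classes) as_peaks(pk("chr1",
                                      seq_along(classes) * 1000,
                                      seq_along(classes) * 1000 + 200,
                                      site_class = classes,
                                      strength = "strong"))
  expect_equal(constellation_label(mk(c("T", "24", "T"))), "T-T-24")
  expect_equal(constellation_label(mk("P")), "P")
  for (perm in list(c("24", "P", "T"), c("T", "P", "24"), c("P", "24", "T")))
    expect_equal(constellation_label(mk(perm)), "P-T-24")
  bad <- as_peaks(pk("chr1", 100, 300, assay = "H3K27ac"))
  expect_error(constellation_label(bad), "site_class")
})

test_that("region ligand dependency needs one significant overlapping peak", {
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000))
  sig <- as_peaks(pk("chr1", 1500, 1800, site_class = "T",
                     strength = "strong", diff_pvalue = 0.01))
  expect_true(region_ligand_dependency(region, sig, 0.05))
  ns <- as_peaks(pk("chr1", c(1500, 1600), c(1800, 1900),
                    assay = "H3K27ac", diff_pvalue = c(0.5, NA)))
  expect_false(region_ligand_dependency(region, ns, 0.05))
  away <- as_peaks(pk("chr1", 5000, 6000, assay = "H3K27ac",
                      diff_pvalue = 0.001))
  expect_false(region_ligand_dependency(region, away, 0.05))
  # solvent-condition peaks never drive dependency
  solv <- as_peaks(pk("chr1", 1500, 1800, assay = "H3K27ac",
                      condition = "solvent", diff_pvalue = 0.001))
  expect_false(region_ligand_dependency(region, solv, 0.05))
})

test_that("enhancer-TSS distances use the midpoint with a promoter zero", {
  a <- anchor1(tss = 100000L)
  reg <- function(s, e) GenomicRanges::GRanges("chr1",
                                               IRanges::IRanges(s + 1, e))
  expect_equal(distance_to_tss(reg(100000 - 50, 100000 + 50), a, 200), 0)
  expect_equal(distance_to_tss(reg(100000 + 24900, 100000 + 25100), a, 200),
               25.0)
  # unsigned: upstream and downstream midpoints are equidistant
  expect_equal(distance_to_tss(reg(100000 - 25100, 100000 - 24900), a, 200),
               25.0)
  expect_error(distance_to_tss(reg(1, 100), anchor1(chrom = "chr9")),
               "different chromosomes")
})

test_that("epigenome classes map (kind, dependency) to 1-4", {
  expect_equal(classify_epigenome("super", TRUE), 1L)
  expect_equal(classify_epigenome("super", FALSE), 2L)
  expect_equal(classify_epigenome("single", TRUE), 3L)
  expect_equal(classify_epigenome("single", FALSE), 4L)
  expect_warning(cls <- classify_epigenome("none", FALSE), "undefined")
  expect_true(is.na(cls))
})

test_that("profiling is invariant to strand flips and coordinate shifts", {
  fx <- key_gene_fixture()
  base <- profile_genes(fx$anchors, fx$peaks, fx$config)
  flipped <- fx$anchors
  flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
  expect_equal(profile_genes(flipped, fx$peaks, fx$config), base)

  shift <- 12345L
  anchors2 <- fx$anchors
  anchors2$tss <- anchors2$tss + shift
  peaks2 <- GenomicRanges::shift(fx$peaks, shift)
  shifted <- profile_genes(anchors2, peaks2, fx$config)
  expect_equal(shifted[setdiff(names(shifted),
                               c("region_start", "region_end"))],
               base[setdiff(names(base), c("region_start", "region_end"))])
  expect_equal(shifted$region_start, base$region_start + shift)
})

test_that("a gene with an empty VDR track gets no enhancer call", {
  fx <- key_gene_fixture()
  m <- S4Vectors::mcols(fx$peaks)
  no_vdr <- fx$peaks[m$assay != "VDR"]
  call <- profile_gene(fx$anchors[1, ], no_vdr, fx$config)
  expect_equal(call$kind, "none")
  expect_true(is.na(call$epigenome_class))
  # super- and single-enhancer calls are mutually exclusive by construction
  full <- profile_genes(fx$anchors, fx$peaks, fx$config)
  expect_true(all(full$kind %in% c("super", "single")))
})
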