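fam_table <- function(...) {
  # fam_table(A = c("f1","f2"), B = "f2") -> one gene per family per species
  sets <- list(...)
  do.call(rbind, lapply(names(sets), function(sp)
    data.frame(family_id = sets[[sp]], species = sp,
               gene_id = paste0(sp, "_", sets[[sp]]),
               stringsAsFactors = FALSE)))
}

test_that("pan and core curves follow set union and intersection", {
  fams <- fam_table(A = c("f1", "f2"), B = c("f2", "f3"))
  pc <- pan_core_curves(fams, c("A", "B"))
  expect_equal(pc$pan, c(2L, 3L))
  expect_equal(pc$core, c(2L, 1L))

  shared <- fam_table(s1 = "f", s2 = "f", s3 = "f", s4 = "f", s5 = "f")
  pc2 <- pan_core_curves(shared, sprintf("s%d", 1:5))
  expect_true(all(pc2$core == 1L))
  expect_true(all(pc2$pan == 1L))

  expect_error(pan_core_curves(fams, c("A", "Z")), "unknown species")
})

test_that("pan is nondecreasing, core nonincreasing, final pan order-invariant", {
  set.seed(21)
  for (rep in 1:20) {
    n_sp <- sample(3:6, 1)
    sp <- sprintf("s%d", seq_len(n_sp))
    args <- setNames(lapply(sp, function(s)
      sprintf("f%d", sort(sample(100, sample(10:60, 1))))), sp)
    fams <- do.call(fam_table, args)
    pc <- pan_core_curves(fams, sp)
    expect_true(all(diff(pc$pan) >= 0))
    expect_true(all(diff(pc$core) <= 0))
    expect_true(all(pc$pan >= pc$core))
    perm <- sample(sp)
    pc2 <- pan_core_curves(fams, perm)
    expect_equal(pc2$pan[n_sp], pc$pan[n_sp])
  }
})

test_that("mean family size averages per-species copy numbers over core families", {
  fams <- rbind(
    data.frame(family_id = "f1", species = c("A", "A", "B"),
               gene_id = c("a1", "a2", "b1")),
    data.frame(family_id = "f2", species = c("A", "B"),
               gene_id = c("a3", "b2")))
  expect_equal(mean_family_size(fams, c("A", "B"), core_families = "f1"), 1.5)
  expect_equal(mean_family_size(fams, c("A", "B")), 1.25)  # both core
  expect_equal(mean_family_size(fams, c("A", "B"), core_families = "f2"), 1)
  expect_true(is.na(mean_family_size(fams, c("A", "B"),
                                     core_families = character(0))))

  # planted mean recovered from a constructed table
  set.seed(5)
  sizes <- sample(1:3, 400, replace = TRUE, prob = c(0.45, 0.47, 0.08))
  rows <- do.call(rbind, lapply(seq_along(sizes), function(i)
    data.frame(family_id = sprintf("f%03d", i), species = "A",
               gene_id = sprintf("f%03d_%d", i, seq_len(sizes[i])))))
  got <- mean_family_size(rows, "A")
  expect_equal(got, mean(sizes))
  expect_lte(abs(got - 1.63), 0.06)
})

test_that("expansion calls depend on copy floor and ratio to other species", {
  copies <- rbind(ankyrin = c(149, 56, 9, 17, 6, 6),
                  specific = c(43, 0, 0, 0, 0, 0),
                  uniform = c(1, 1, 1, 1, 1, 1))
  colnames(copies) <- c("focal", sprintf("sp%d", 1:5))
  r <- detect_expansions(copies, "focal")
  # 149 / 56 = 2.66: flagged at the default 2.5x ratio, threshold-sensitive
  expect_true(r$expanded[r$family_id == "ankyrin"])
  # ...but not when the ratio is tightened to 3
  r2 <- detect_expansions(copies, "focal", ratio = 3)
  expect_false(r2$expanded[r2$family_id == "ankyrin"])
  # species-specific family: zeros count as 0.5, so 43 passes easily
  expect_true(r$expanded[r$family_id == "specific"])
  expect_false(r$expanded[r$family_id == "uniform"])

  # invariant to permuting the non-focal columns
  perm <- copies[, c("focal", sample(sprintf("sp%d", 1:5)))]
  expect_equal(detect_expansions(perm, "focal")$expanded, r$expanded)
})

test_that("term enrichment gives exact tails, Bonferroni, and folds", {
  background <- sprintf("g%03d", 1:100)
  term_map <- data.frame(gene_id = background[1:10], term = "T1")
  selected <- c(background[1:5], background[51:55])  # k=5, n=10, K=10
  r <- go_enrichment(selected, background, term_map)
  expect_equal(r$p_raw, hyper_tail_enum(5, 10, 100, 10))
  expect_equal(r$fold, 5)
  expect_equal(r$p_bonferroni, r$p_raw)  # single tested term

  # k = K = n = N: tail is exactly 1
  r2 <- go_enrichment(c("a", "b"), c("a", "b"),
                      data.frame(gene_id = c("a", "b"), term = "T"))
  expect_equal(r2$p_raw, 1)

  # Bonferroni multiplies by the number of tested terms, capped at 1
  tm <- data.frame(gene_id = rep(background[1:10], 3),
                   term = rep(c("T1", "T2", "T3"), each = 10))
  r3 <- go_enrichment(background[1:5], background, tm)
  expect_equal(r3$p_bonferroni, pmin(1, r3$p_raw * 3))

  expect_equal(nrow(go_enrichment(character(0), background, term_map)), 0L)
})

test_that("regional expression enrichment is relative to the region", {
  region <- data.frame(gene_id = sprintf("r%d", 1:20),
                       est_count = rep(c(5L, 0L), c(15, 5)),   # 75% expressed
                       category = rep(c("cat_hi", "cat_same"), 10))
  # cat_hi genes all expressed (10/10), cat_same mirrors the region
  region$est_count[region$category == "cat_hi"] <- 3L
  region$est_count[region$category == "cat_same"] <- rep(c(2L, 0L), 5)
  all_genes <- rbind(region,
                     data.frame(gene_id = sprintf("o%d", 1:60),
                                est_count = rep(c(1L, 0L, 0L, 0L), 15),
                                category = NA))
  r <- relative_expression_enrichment(region, all_genes)
  f_region <- mean(region$est_count > 0)
  expect_equal(r$table$enrichment[r$table$category == "cat_hi"],
               1 / f_region)
  expect_equal(r$table$enrichment[r$table$category == "cat_same"],
               0.5 / f_region)
  expect_equal(r$correction_fold,
               f_region / mean(all_genes$est_count > 0))
})

test_that("a planted 1.6-fold expression excess is recovered as the correction fold", {
  set.seed(77)
  # region expressed fraction 0.75 (geometric mean 3), background 0.457
  # (mean 0.84), region = 200 of 5,000 genes -> region/genome ratio = 1.60
  region <- data.frame(gene_id = sprintf("r%d", 1:200),
                       est_count = rnbinom(200, mu = 3, size = 1),
                       category = NA)
  rest <- data.frame(gene_id = sprintf("o%d", 1:4800),
                     est_count = rnbinom(4800, mu = 0.84, size = 1),
                     category = NA)
  r <- relative_expression_enrichment(region, rbind(region, rest))
  expect_lte(abs(r$correction_fold - 1.6), 0.1)
})

test_that("per-chromosome HGT folds compare against the genome average", {
  genes <- data.frame(gene_id = sprintf("g%d", 1:100),
                      chrom = rep(c("cX", "cY"), c(10, 90)),
                      start = 1:100, end = 2:101)
  calls <- data.frame(gene_id = sprintf("g%d", c(1, 2, seq(11, 90, 10))),
                      klass = "hgt_eukaryote")
  d <- hgt_distribution(calls, genes)
  # genome: 10/100; cX: 2/10 -> fold 2
  expect_equal(d$fold[d$bin == "cX"], 2)
  expect_equal(sum(d$n_hgt), 10)

  none <- hgt_distribution(data.frame(gene_id = "g1", klass = "viridiplantae"),
                           genes)
  expect_true(all(none$fraction == 0))
  expect_true(all(is.na(none$fold)))
})

test_that("uniformly placed HGT gives folds near one on every chromosome", {
  set.seed(13)
  folds <- c()
  for (s in 1:10) {
    genes <- data.frame(gene_id = sprintf("g%d", 1:400),
                        chrom = rep(sprintf("c%d", 1:4), each = 100),
                        start = 1:400, end = 2:401)
    hgt <- sample(genes$gene_id, 40)
    calls <- data.frame(gene_id = hgt, klass = "hgt_eukaryote")
    d <- hgt_distribution(calls, genes)
    folds <- c(folds, d$fold)
  }
  expect_lte(abs(mean(folds) - 1), 0.05)
  expect_true(all(folds > 0.2 & folds < 2.5))
})
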