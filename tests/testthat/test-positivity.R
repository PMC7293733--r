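# random multi-cohort fixture for property checks
random_fixture <- function(seed, n_genes = 4, cohorts = c("A", "B", "C")) {
  set.seed(seed)
  n_per <- sample(10:30, length(cohorts), replace = TRUE)
  n <- sum(n_per)
  genes <- paste0("G", seq_len(n_genes))
  m <- matrix(rlnorm(n_genes * n, meanlog = 8, sdlog = 1.2), n_genes, n,
              dimnames = list(genes, paste0("s", seq_len(n))))
  a <- data.frame(sample_id = colnames(m),
                  cohort = rep(cohorts, n_per),
                  tissue = sample(c("tumor", "normal"), n, replace = TRUE,
                                  prob = c(0.85, 0.15)),
                  stringsAsFactors = FALSE)
  # guarantee every cohort at least one tumor
  for (co in cohorts) a$tissue[which(a$cohort == co)[1]] <- "tumor"
  list(m = m, a = a, genes = genes)
}

test_that("the union score is the max over the gene set", {
  m <- matrix(c(5000, 100, 7, 80, 900, 60), 3, 2,
              dimnames = list(c("FGFR1", "FGFR3", "FGFR4"), c("s1", "s2")))
  sc <- sample_score(m, c("FGFR1", "FGFR3"))
  expect_equal(unname(sc), c(5000, 900))
  expect_equal(unname(sample_score(m, "FGFR4")), c(7, 60))
  expect_error(sample_score(m, c("FGFR1", "FGFR2")), "FGFR2")

  # (score >= t) <=> (some member gene >= t) at any threshold
  for (t in c(0, 50, 99, 900, 5001))
    expect_equal(sc >= t,
                 apply(m[c("FGFR1", "FGFR3"), ] >= t, 2, any))
})

test_that("calibration on distinct scores hits the target exactly", {
  set.seed(1)
  n <- 100
  m <- matrix(c(sample(seq(1000, 99000, by = 7), n), runif(n, 0, 10)),
              2, n, byrow = TRUE,
              dimnames = list(c("FGFR1", "FGFR3"), paste0("s", 1:n)))
  a <- data.frame(sample_id = colnames(m), cohort = "BLCA", tissue = "tumor")
  cal <- calibrate_cutoff(m, a, positivity_config(target_prevalence = 0.42))
  expect_equal(cal$achieved_reference_ratio, 0.42)
  expect_equal(cal$cutoff,
               unname(sort(m["FGFR1", ], decreasing = TRUE)[42]))
  expect_true(cal$cutoff %in% m["FGFR1", ])  # an observed value
})

test_that("ties at the cutoff raise the achieved ratio, matching enumeration", {
  scores <- c(rep(100, 10), rep(50, 30), rep(10, 60))  # tie block at rank 42
  m <- matrix(c(scores, rep(0, 100)), 2, 100, byrow = TRUE,
              dimnames = list(c("FGFR1", "FGFR3"), paste0("s", 1:100)))
  a <- data.frame(sample_id = colnames(m), cohort = "BLCA", tissue = "tumor")
  cal <- calibrate_cutoff(m, a, positivity_config(target_prevalence = 0.42))
  expect_equal(cal$cutoff, 50)
  expect_equal(cal$achieved_reference_ratio, 0.4)  # tie-inclusive 40/100
  # brute force over every candidate cutoff: no observed value does better
  best <- min(abs(vapply(unique(scores),
                         function(c0) mean(scores >= c0), numeric(1)) - 0.42))
  expect_equal(abs(cal$achieved_reference_ratio - 0.42), best)
})

test_that("unattainable prevalence and missing reference cohort error out", {
  m <- matrix(1:4 * 100, 1, 4,
              dimnames = list("FGFR1", paste0("s", 1:4)))
  a <- data.frame(sample_id = colnames(m), cohort = "BLCA", tissue = "tumor")
  expect_error(calibrate_cutoff(m, a,
                                positivity_config(gene_set = "FGFR1",
                                                  target_prevalence = 0.05)),
               "unattainable")
  expect_error(calibrate_cutoff(m, a,
                                positivity_config(gene_set = "FGFR1",
                                                  reference_cohort = "CHOL")),
               "CHOL")
})

test_that("positive ratio is simple count arithmetic with inclusive cutoff", {
  set.seed(2)
  n <- 36  # cholangiocarcinoma-sized cohort
  m <- matrix(rlnorm(n, 8, 1), 1, n,
              dimnames = list("FGFR1", paste0("s", 1:n)))
  a <- data.frame(sample_id = colnames(m), cohort = "CHOL", tissue = "tumor")
  cut7 <- sort(m["FGFR1", ], decreasing = TRUE)[7]
  expect_equal(positive_ratio(m, a, "CHOL", "FGFR1", cut7), 7 / 36)
  expect_equal(positive_ratio(m, a, "CHOL", "FGFR1", 0), 1)
  expect_equal(positive_ratio(m, a, "CHOL", "FGFR1", max(m) * 2), 0)
  a2 <- a; a2$tissue <- "normal"
  expect_warning(r <- positive_ratio(m, a2, "CHOL", "FGFR1", 100),
                 "no tumor")
  expect_true(is.na(r))
})

test_that("positivity invariants hold across 50 random fixtures", {
  for (s in 1:50) {
    fx <- random_fixture(s)
    set.seed(1000 + s)
    cuts <- sort(c(0, stats::quantile(fx$m, c(0.25, 0.5, 0.9)),
                   max(fx$m) * 1.01))
    gset <- sample(fx$genes, 2)
    co <- sample(unique(fx$a$cohort), 1)
    ratios <- vapply(cuts, function(ct)
      positive_ratio(fx$m, fx$a, co, gset, ct), numeric(1))
    # monotone non-increasing in the cutoff
    expect_true(all(diff(ratios) <= 1e-12))
    ct <- cuts[3]
    member <- vapply(gset, function(g)
      positive_ratio(fx$m, fx$a, co, g, ct), numeric(1))
    set_ratio <- positive_ratio(fx$m, fx$a, co, gset, ct)
    # union bounds: max(member) <= set <= sum(member)
    expect_gte(set_ratio + 1e-12, max(member))
    expect_lte(set_ratio, sum(member) + 1e-12)
    # enlarging the gene set never decreases the ratio
    expect_gte(positive_ratio(fx$m, fx$a, co, fx$genes, ct) + 1e-12,
               set_ratio)
    # scale equivariance: multiply expression and cutoff by c > 0
    expect_equal(positive_ratio(fx$m * 3.7, fx$a, co, gset, ct * 3.7),
                 set_ratio)
  }
})

test_that("full positivity scan is self-consistent and ranks a shifted cohort", {
  g <- default_gene_table()
  g_hi <- g
  g_hi$base_log2_mean <- g_hi$base_log2_mean + 2 * g_hi$log2_sd
  d <- generate_pancancer(list(
    cohort_spec("BLCA", 407, 0, genes = g, seed = 21),
    cohort_spec("CHOL", 36, 0, genes = g_hi, seed = 22),
    cohort_spec("PAAD", 178, 0, genes = g, seed = 23)))
  pos <- positivity_scan(d$expression, d$annotation, positivity_config(),
                         bootstrap_reps = 200, seed = 21)
  tab <- pos$table
  ref <- tab[tab$cohort == "BLCA", ]
  # recomputing the reference ratio returns the achieved ratio exactly
  expect_equal(ref$set_ratio, pos$achieved_reference_ratio)
  expect_lte(abs(ref$set_ratio - 0.42), 1 / 407)
  # the cohort with +2 SD expression exceeds the reference
  expect_gt(tab$set_ratio[tab$cohort == "CHOL"], ref$set_ratio)
  # union bounds per cohort over the report genes in the set
  for (i in seq_len(nrow(tab))) {
    expect_gte(tab$set_ratio[i] + 1e-12, max(tab$FGFR1[i], tab$FGFR3[i]))
    expect_lte(tab$set_ratio[i], tab$FGFR1[i] + tab$FGFR3[i] + 1e-12)
  }
  expect_true(all(tab$set_ratio_lo <= tab$set_ratio + 1e-12 &
                    tab$set_ratio <= tab$set_ratio_hi + 1e-12))
  # bootstrap is seeded: identical reruns match
  pos2 <- positivity_scan(d$expression, d$annotation, positivity_config(),
                          bootstrap_reps = 200, seed = 21)
  expect_identical(pos$table, pos2$table)
})
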