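test_that("constant genes score zero and hand-computed fits match", {
  # two genes, 4 time points, single replicate semantics approximated by
  # 2 replicates with identical values
  time <- rep(c(1, 2, 3, 4), each = 2)
  X <- rbind(gene1 = rep(5, 8),
             gene2 = rep(c(0, 0, 1, 1), each = 2))
  st <- tiny_study(`colnames<-`(X, sprintf("s%d", 1:8)), time)
  stat <- timecourse_statistic(st, spline_df = 1)
  expect_equal(unname(stat["gene1"]), 0)
  # closed-form least squares on (0,0,1,1) against a linear-in-time fit
  x <- st$matrix["gene2", ]
  D <- cbind(1, splines::ns(st$samples$time_h, df = 1))
  beta <- solve(crossprod(D), crossprod(D, x))
  rss1 <- sum((x - D %*% beta)^2)
  rss0 <- sum((x - mean(x))^2)
  expect_equal(unname(stat["gene2"]), (rss0 - rss1) / rss1)
})

test_that("the F-like statistic is location invariant and scale free", {
  spec <- expression_sim_spec(n_genes = 50, frac_deg = 0.5, seed = 5)
  sim <- simulate_timecourse(spec)
  base <- timecourse_statistic(sim$study)
  shifted <- sim$study
  shifted$matrix <- shifted$matrix + 3
  expect_equal(timecourse_statistic(shifted), base)
  scaled <- sim$study
  scaled$matrix <- scaled$matrix * 2.5
  expect_equal(timecourse_statistic(scaled), base)
})

test_that("a planted DEG with a 3-sigma bump outscores the null distribution", {
  spec <- expression_sim_spec(n_genes = 2000, frac_deg = 0.05, effect_sd = 3,
                              seed = 12)
  sim <- simulate_timecourse(spec)
  stat <- timecourse_statistic(sim$study)
  null_stats <- stat[sim$truth$status == "null"]
  deg_stats <- stat[sim$truth$status == "deg" & sim$truth$phase == "a"]
  expect_gt(median(deg_stats), quantile(null_stats, 0.99))
})

test_that("the ODP variant separates planted signal from null genes", {
  spec <- expression_sim_spec(n_genes = 500, frac_deg = 0.1, effect_sd = 3,
                              seed = 13)
  sim <- simulate_timecourse(spec)
  stat <- timecourse_statistic(sim$study, method = "odp")
  is_deg <- sim$truth$status == "deg"
  expect_gt(median(stat[is_deg]), quantile(stat[!is_deg], 0.95))
})

test_that("too few time points for the spline basis is an error", {
  spec <- expression_sim_spec(n_genes = 10, time_points = c(1, 2, 3), seed = 1)
  sim <- simulate_timecourse(spec)
  expect_error(timecourse_statistic(sim$study, spline_df = 3),
               "distinct time points")
})

test_that("permutation p-values are uniform on pure noise and deterministic", {
  spec <- expression_sim_spec(n_genes = 2000, frac_deg = 0, seed = 1)
  sim <- simulate_timecourse(spec)
  p <- permutation_null(sim$study, B = 200, seed = 1)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
  p2 <- permutation_null(sim$study, B = 200, seed = 1)
  expect_identical(p, p2)
  expect_error(permutation_null(sim$study, B = 10), "B must be >= 50")
})

test_that("genes with statistic zero receive p-values of one", {
  time <- rep(c(1, 2, 3, 4, 5, 6), each = 2)
  X <- matrix(rnorm(12 * 20), 20, 12,
              dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:12)))
  X[1, ] <- 7   # constant gene: statistic 0
  st <- tiny_study(X, time)
  p <- permutation_null(st, B = 100, seed = 2)
  expect_gte(p["g1"], 1 - 1 / 101)
})

test_that("Storey q-values reduce to Benjamini-Hochberg when pi0 is 1", {
  set.seed(31)
  for (rep in 1:100) {
    p <- runif(sample(20:200, 1))^sample(1:3, 1)
    q <- storey_qvalues(p, pi0 = 1)
    expect_identical(as.numeric(q), p.adjust(p, method = "BH"))
  }
})

test_that("q-values are monotone in p and respect the pi0 estimate", {
  p <- c(0.01, 0.02, 0.5, 0.9, 1, 1)
  q <- storey_qvalues(p, lambda = 0.5)
  expect_equal(attr(q, "pi0"), min(1, sum(p > 0.5) / (6 * 0.5)))
  expect_true(all(diff(as.numeric(q)[order(p)]) >= -1e-12))
  expect_equal(as.numeric(storey_qvalues(rep(1, 5))), rep(1, 5))
  expect_error(storey_qvalues(numeric(0)), "empty")
})

test_that("DEG selection reports counts and chip percentages", {
  sel <- select_degs(c(a = 0.0005, b = 0.5))
  expect_equal(sel$n, 1L)
  expect_equal(sel$genes, "a")
  # the published denominator arithmetic: 404 of 6494 genes is 6.22%
  q <- c(rep(0, 404), rep(1, 6494 - 404))
  sel2 <- select_degs(q, threshold = 0.001)
  expect_equal(sel2$n, 404L)
  expect_equal(round(sel2$percent, 2), 6.22)
  expect_equal(select_degs(numeric(0))$n, 0L)
})

test_that("phase assignment standardizes, clusters and labels by profile peak", {
  time <- rep(c(12, 24, 36, 48, 60, 72), each = 2)
  set.seed(41)
  up_a <- rep(c(1, 1, 1, 0, 0, 0), each = 2)
  up_b <- rep(c(0, 0, 0, 1, 1, 0), each = 2)
  X <- rbind(matrix(rep(up_a, 5), 5, 12, byrow = TRUE),
             matrix(rep(up_b, 5), 5, 12, byrow = TRUE)) +
    matrix(rnorm(120, 0, 0.05), 10, 12)
  dimnames(X) <- list(sprintf("g%d", 1:10), sprintf("s%d", 1:12))
  ph <- assign_phases(X, time, phase_breaks = c(36, 60))
  expect_equal(unname(ph$assignments$phase[1:5]), rep("a", 5))
  expect_equal(unname(ph$assignments$phase[6:10]), rep("b", 5))
  Z <- ph$standardized
  expect_equal(unname(rowMeans(Z)), rep(0, 10), tolerance = 1e-9)
  expect_equal(unname(apply(Z, 1, sd)), rep(1, 10), tolerance = 1e-9)

  Xc <- X; Xc[1, ] <- 3
  expect_error(assign_phases(Xc, time), "g1")
})

test_that("phase labels recover planted phase structure at the study's proportions", {
  # 46 phase-a and 10 phase-b genes (the published 459/104 split at 1/10 scale)
  time <- rep(c(12, 24, 36, 48, 60, 72), each = 2)
  set.seed(42)
  profs <- rbind(
    matrix(rep(rep(c(1, 1, 1, 0, 0, 0), each = 2), 46), 46, 12, byrow = TRUE),
    matrix(rep(rep(c(0, 0, 0, 1, 1, 0), each = 2), 10), 10, 12, byrow = TRUE))
  X <- profs * 0.75 + matrix(rnorm(56 * 12, 0, 0.25), 56, 12)
  dimnames(X) <- list(sprintf("g%d", 1:56), sprintf("s%d", 1:12))
  truth <- c(rep("a", 46), rep("b", 10))
  ph <- assign_phases(X, time, phase_breaks = c(36, 60))
  acc <- mean(ph$assignments$phase == truth)
  expect_gte(acc, 0.9)
})

test_that("the COG representation rule flags the published table rows", {
  expect_equal(cog_flag(4.79, 9.90), "over")    # energy production
  expect_equal(cog_flag(1.27, 2.97), "over")    # nucleotide transport
  expect_equal(cog_flag(7.20, 2.23), "under")   # transcription
  expect_equal(cog_flag(5, 10), "over")         # boundary: exactly 2x is over
  expect_equal(cog_flag(5, 2.5), "under")       # boundary: exactly half is under
  expect_equal(cog_flag(5, 6), "neither")
  expect_equal(cog_flag(0, 3), "over")          # deg > 0 with zero chip share
  expect_equal(cog_flag(3, 0), "neither")       # zero deg percentage
})

test_that("COG tables percentage both sides over their own denominators", {
  ann <- tibble::tibble(gene = sprintf("g%d", 1:100),
                        cog_category = rep(c("A", "B", "C", NA), 25))
  degs <- sprintf("g%d", seq(1, 40, by = 4))  # all in category A
  tab <- cog_representation(degs, ann)
  a <- tab[tab$cog_category == "A", ]
  expect_equal(a$chip_percent, 25)
  expect_equal(a$deg_percent, 100)
  expect_equal(a$flag, "over")
  expect_equal(sum(tab$chip_percent), 100)
  expect_equal(sum(tab$deg_percent), 100)
})

test_that("timecourse_de ties the stages together with tidy/glance access", {
  spec <- expression_sim_spec(n_genes = 300, frac_deg = 0.1, effect_sd = 4,
                              seed = 51)
  sim <- simulate_timecourse(spec)
  de <- timecourse_de(sim$study, B = 100, seed = 52, q_threshold = 0.05)
  td <- tidy(de)
  expect_equal(nrow(td), 300L)
  expect_true(all(c("gene", "statistic", "p", "q", "phase") %in% names(td)))
  expect_true(all(td$phase[td$q <= 0.05] != "none" | de$degs$n < 2))
  expect_true(all(td$phase[td$q > 0.05] == "none"))
  gl <- glance(de)
  expect_equal(gl$n_degs, de$degs$n)
  expect_s3_class(autoplot(de), "ggplot")
})

test_that("DEG recall at q <= 0.05 clearly beats a label-shuffled control", {
  # fine-grained fermentation sampling: 13 points at 6-h intervals (12-84 h),
  # triplicate arrays; 10% DEGs with bumps of 2 noise-sd
  rec <- shuf_rec <- numeric(3)
  for (i in 1:3) {
    spec <- expression_sim_spec(n_genes = 2000,
                                time_points = seq(12, 84, by = 6),
                                replicates = 3, frac_deg = 0.1,
                                effect_sd = 2, seed = 60 + i)
    sim <- simulate_timecourse(spec)
    p <- permutation_null(sim$study, B = 100, seed = 70 + i)
    deg <- select_degs(storey_qvalues(p), 0.05)
    truth_deg <- sim$truth$gene[sim$truth$status == "deg"]
    rec[i] <- mean(truth_deg %in% deg$genes)
    set.seed(80 + i)
    shuffled <- sample(sim$truth$gene, length(truth_deg))
    shuf_rec[i] <- mean(shuffled %in% deg$genes)
  }
  expect_gte(median(rec) - median(shuf_rec), 0.5)
})
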