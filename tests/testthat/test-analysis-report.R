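# Selection, fold-change ranking, statistical tests, aligned axis, plots.

test_that("metadata and feature-range selections compose by intersection", {
  proj <- toy_project(n_cells = 8)
  ctrl <- select_cells(proj, meta = list(treatment = "ctrl"))
  expect_length(ctrl, 4L)
  # conjunction equals the intersection of the individual selections
  hi <- select_cells(proj, ranges = list(score = c(3, 8)))
  both <- select_cells(proj, meta = list(treatment = "ctrl"),
                       ranges = list(score = c(3, 8)))
  expect_setequal(both, intersect(ctrl, hi))
  # empty predicate selects everything
  expect_setequal(select_cells(proj), names(proj$cells))
  expect_error(select_cells(proj, meta = list(oligo = "x")), "valid keys")
  expect_error(select_cells(proj, ranges = list(nope = c(0, 1))),
               "valid features")
  expect_warning(select_cells(proj, ranges = list(score = c(-5, -1))),
                 "empty")
})

test_that("fold-change table covers the registry and recovers constructed folds", {
  proj <- toy_project(gain = 2)
  fc <- fold_change_report(proj)
  expect_setequal(fc$feature, proj$ts_features)       # completeness
  expect_equal(fc$fold_ip[fc$feature == "f1"], 2, tolerance = 0.01)
  expect_equal(fc$fold_ma[fc$feature == "f1"], 2, tolerance = 0.01)
  expect_equal(fc$fold_ip[fc$feature == "f2"], 1, tolerance = 1e-12)
  # constant feature ranks below the changing one
  expect_equal(fc$feature[1], "f1")
})

test_that("the HTML report is written with its table and figures", {
  proj <- toy_project()
  dir <- file.path(withr::local_tempdir(), "report")
  fold_change_report(proj, out_dir = dir)
  expect_true(file.exists(file.path(dir, "index.html")))
  html <- readLines(file.path(dir, "index.html"))
  expect_true(any(grepl("f1", html)))
  expect_gt(length(list.files(dir, pattern = "\\.png$")), 0L)
})

test_that("single-feature tests behave on identical and well-separated groups", {
  set.seed(10)
  a <- rnorm(50); b <- rnorm(50, 5)
  same <- list(g1 = a, g2 = a)
  r <- run_single_feature_tests(same, "t_test")
  expect_gt(r$p, 0.99)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  for (tst in c("t_test", "anova", "wilcoxon", "kruskal_wallis")) {
    r <- run_single_feature_tests(list(g1 = a, g2 = b), tst)
    expect_lt(r$p, 1e-6)
    expect_equal(r$n_g1, 50)
  }
  expect_error(run_single_feature_tests(list(a, b, a), "t_test"), "exactly 2")
  expect_warning(run_single_feature_tests(list(g1 = a, g2 = b, g3 = 1),
                                          "anova"), "n < 2")
})

test_that("feature test tables carry raw and BH-adjusted p-values", {
  proj <- toy_project(n_cells = 12)
  groups <- list(ctrl = select_cells(proj, meta = list(treatment = "ctrl")),
                 drug = select_cells(proj, meta = list(treatment = "drug")))
  tab <- feature_test_table(proj, groups, test = "t_test")
  expect_setequal(tab$feature, proj$single_features)
  expect_true(all(c("p", "p_adj") %in% names(tab)))
  expect_true(all(tab$p_adj >= tab$p, na.rm = TRUE))
})

test_that("two-way treatment x time ANOVA separates offsets from interactions", {
  set.seed(44)
  base <- matrix(rnorm(10 * 8, 50, 1), 10, 8)
  # identical populations: treatment effect absent
  r0 <- run_timeseries_anova(list(g1 = base, g2 = base + rnorm(80, 0, 1)))
  expect_gt(r0$p[r0$factor == "treatment"], 0.01)
  # constant offset: treatment significant, interaction not
  r1 <- run_timeseries_anova(list(g1 = base, g2 = base + 5))
  expect_lt(r1$p[r1$factor == "treatment"], 1e-6)
  expect_gt(r1$p[r1$factor == "interaction"], 0.05)
  expect_error(run_timeseries_anova(list(g1 = base[, 1, drop = FALSE],
                                         g2 = base[, 1, drop = FALSE])),
               "2 time points")
})

test_that("the aligned axis is monotone and anchor-preserving for random windows", {
  set.seed(17)
  syncs <- lapply(1:20, function(i) {
    n <- sample(40:90, 1)
    ip <- sample(5:20, 1)
    ma <- ip + sample(3:15, 1)
    sync_states(n, ip = ip, ma = ma)
  })
  axis <- aligned_time_axis(syncs)
  for (s in syncs) {
    n <- length(s$states)
    pos <- map_to_axis(seq_len(n), s, axis)     # map the frame index itself
    expect_equal(pos[axis$ip_pos], s$ip)        # IP lands on the IP slot
    expect_equal(pos[axis$ma_pos], s$ma)        # MA lands on the MA slot
    expect_true(all(diff(na.omit(pos)) > 0))    # strictly monotone mapping
  }
})

test_that("project-level ANOVA and plots run on the toy project", {
  proj <- toy_project(n_cells = 8)
  groups <- list(ctrl = select_cells(proj, meta = list(treatment = "ctrl")),
                 drug = select_cells(proj, meta = list(treatment = "drug")))
  r <- run_timeseries_anova_project(proj, groups, "f1")
  expect_equal(nrow(r), 3L)

  f <- withr::local_tempfile(fileext = ".png")
  h <- render_plot(proj, "f1", "heatmap", file = f)
  expect_true(file.exists(f))
  expect_equal(nrow(h$data$all), length(proj$cells))  # one row per cell
  expect_false(is.null(h$anchors))
  # duplicated single cell: sd band of width zero
  one <- names(proj$cells)[1]
  m <- render_plot(proj, "f1", "mean_sd", ids = c(one, one),
                   file = withr::local_tempfile(fileext = ".png"))
  mm <- m$data[[1]]
  expect_equal(apply(mm, 2, sd), rep(0, ncol(mm)), ignore_attr = TRUE)
  # grouped plots honour the grouping
  g <- render_plot(proj, "score", "box", ids_by_group = groups,
                   file = withr::local_tempfile(fileext = ".png"))
  expect_length(g$data, 2L)
  for (k in c("violin", "histogram"))
    render_plot(proj, "score", k, ids_by_group = groups,
                file = withr::local_tempfile(fileext = ".png"))
  expect_error(render_plot(cell_project(list()), "f1", "heatmap",
                           file = withr::local_tempfile()), "synchronized|cells")
})
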