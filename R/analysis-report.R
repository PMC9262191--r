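# Data selection, grouped statistics, fold-change feature ranking with HTML
# report, and the aligned-time-axis visualizations.

#' Select cells by metadata equality and single-feature ranges
#'
#' Predicates compose by intersection: a cell is selected when every metadata
#' key matches one of the allowed values and every referenced single feature
#' lies inside its closed range. An empty predicate selects all cells; an
#' empty result is allowed (with a warning). Unknown keys raise an error
#' listing the valid ones.
#'
#' @param project a [cell_project()].
#' @param meta named list, e.g. `list(treatment = "Scrambled")`; each element
#'   is the set of accepted values for that metadata key.
#' @param ranges named list of `c(min, max)` over single features, e.g.
#'   `list(interphase_mean_int = c(40, 46))`.
#' @return character vector of selected cell ids (deterministic order).
#' @export
select_cells <- function(project, meta = list(), ranges = list()) {
  stopifnot(inherits(project, "cell_project"))
  ids <- names(project$cells)
  meta_keys <- unique(unlist(lapply(project$cells,
                                    function(cell) names(cell$metadata))))
  bad <- setdiff(names(meta), meta_keys)
  if (length(bad))
    stop_mitotraj("unknown metadata key(s): ", paste(bad, collapse = ", "),
                  "; valid keys: ", paste(meta_keys, collapse = ", "))
  bad <- setdiff(names(ranges), project$single_features)
  if (length(bad))
    stop_mitotraj("unknown single feature(s): ", paste(bad, collapse = ", "),
                  "; valid features: ",
                  paste(project$single_features, collapse = ", "))
  keep <- vapply(ids, function(id) {
    cell <- project$cells[[id]]
    for (k in names(meta))
      if (!(cell$metadata[[k]] %in% meta[[k]])) return(FALSE)
    for (k in names(ranges)) {
      v <- cell$single[[k]]
      if (is.na(v) || v < ranges[[k]][1] || v > ranges[[k]][2]) return(FALSE)
    }
    TRUE
  }, TRUE)
  out <- ids[keep]
  if (length(out) == 0L) warning("selection is empty")
  out
}

#' Common three-segment plotting time axis
#'
#' Because the duration of prophase..metaphase differs between cells, frames
#' cannot be compared by raw index. The common axis has three segments:
#' an interphase block (cells right-aligned on the IP anchor), a fixed-length
#' IP-to-MA block onto which each cell's variable-length mitotic segment is
#' stretched uniformly, and a post-MA block (left-aligned on MA). IP and MA
#' map to the same axis position for every cell and the mapping is monotone.
#'
#' @param syncs list of valid [sync_states()].
#' @param n_mid number of axis slots for the IP-to-MA block (default: the
#'   median observed IP-to-MA length).
#' @return object of class `aligned_time_axis`: list with `n_pre`, `n_mid`,
#'   `n_post`, `length`, `ip_pos`, `ma_pos`.
#' @export
aligned_time_axis <- function(syncs, n_mid = NULL) {
  syncs <- Filter(function(s) isTRUE(s$valid), syncs)
  if (length(syncs) == 0L) stop_mitotraj("no synchronized cells")
  ips <- vapply(syncs, `[[`, 0L, "ip")
  mas <- vapply(syncs, `[[`, 0L, "ma")
  ns <- vapply(syncs, function(s) length(s$states), 0L)
  n_pre <- max(ips - 1L)
  if (is.null(n_mid)) n_mid <- max(2L, round(median(mas - ips)))
  n_post <- max(ns - mas + 1L)
  structure(list(n_pre = n_pre, n_mid = as.integer(n_mid), n_post = n_post,
                 length = n_pre + n_mid + n_post,
                 ip_pos = n_pre + 1L, ma_pos = n_pre + n_mid + 1L),
            class = "aligned_time_axis")
}

#' Map one cell's series onto an aligned axis
#'
#' @param x numeric series (one value per trajectory frame).
#' @param sync the cell's valid [sync_states()].
#' @param axis an [aligned_time_axis()].
#' @return numeric vector of length `axis$length` with `NA` padding.
#' @export
map_to_axis <- function(x, sync, axis) {
  stopifnot(inherits(axis, "aligned_time_axis"), isTRUE(sync$valid))
  out <- rep(NA_real_, axis$length)
  ip <- sync$ip; ma <- sync$ma; n <- length(x)
  pre <- x[seq_len(ip - 1L)]
  out[(axis$n_pre - length(pre) + 1L):axis$n_pre] <- pre
  mid <- x[ip:(ma - 1L)]
  out[axis$ip_pos:(axis$ma_pos - 1L)] <-
    if (length(mid) == 1L) rep(mid, axis$n_mid) else
      stats::approx(seq_along(mid), mid, n = axis$n_mid)$y
  post <- x[ma:n]
  post <- post[seq_len(min(length(post), axis$n_post))]
  out[axis$ma_pos:(axis$ma_pos + length(post) - 1L)] <- post
  out
}

# Aligned matrix (cells x axis slots) of one time-series feature.
.aligned_feature_matrix <- function(project, ids, feature, axis = NULL) {
  cells <- project$cells[ids]
  cells <- Filter(function(cell) isTRUE(cell$sync$valid), cells)
  if (length(cells) == 0L)
    stop_mitotraj("temporal analysis requires synchronized cells")
  if (is.null(axis))
    axis <- aligned_time_axis(lapply(cells, `[[`, "sync"))
  m <- t(vapply(cells, function(cell)
    map_to_axis(cell$ts[, feature], cell$sync, axis), numeric(axis$length)))
  rownames(m) <- names(cells)
  list(matrix = m, axis = axis)
}

#' Fold-change feature ranking and report
#'
#' For each time-series feature and each synchronized cell, the n-fold change
#' from the cell's interphase average to the average of the first `window`
#' prophase (state-2) frames (`fold_ip`) and the first `window` late-anaphase
#' (state-3) frames (`fold_ma`) is computed. The table reports per-feature
#' summary statistics (min, max, mean, sd, median of the per-cell feature
#' means) and the mean folds, ranked by the larger absolute log2 fold; a
#' feature with zero interphase mean is listed with missing folds. With
#' `out_dir` a static HTML report embedding the ranked table and one aligned
#' mean-curve PNG per feature is written.
#'
#' @param project a [cell_project()].
#' @param ids cell ids (default: all synchronized cells).
#' @param window number of frames averaged at each anchor (default 2).
#' @param out_dir optional report output directory.
#' @return the ranked data.frame (one row per feature in the registry),
#'   with attribute `per_cell` holding the per-cell folds.
#' @export
fold_change_report <- function(project, ids = NULL, window = 2L,
                               out_dir = NULL) {
  stopifnot(inherits(project, "cell_project"))
  ids <- ids %||% names(project$cells)
  cells <- Filter(function(cell) isTRUE(cell$sync$valid), project$cells[ids])
  if (length(cells) == 0L) stop_mitotraj("no synchronized cells selected")
  feats <- project$ts_features
  per_cell <- do.call(rbind, lapply(cells, function(cell) {
    st <- cell$sync$states
    i_int <- which(st == 1L)
    i_ip <- head(which(st == 2L), window)
    i_ma <- head(which(st == 3L), window)
    do.call(rbind, lapply(feats, function(f) {
      v <- cell$ts[, f]
      mu <- mean(v[i_int], na.rm = TRUE)
      data.frame(cell = cell$id, feature = f,
                 interphase_mean = mu,
                 overall_mean = mean(v, na.rm = TRUE),
                 fold_ip = if (is.finite(mu) && mu != 0)
                   mean(v[i_ip], na.rm = TRUE) / mu else NA_real_,
                 fold_ma = if (is.finite(mu) && mu != 0)
                   mean(v[i_ma], na.rm = TRUE) / mu else NA_real_)
    }))
  }))
  agg <- do.call(rbind, lapply(feats, function(f) {
    d <- per_cell[per_cell$feature == f, ]
    v <- d$overall_mean
    data.frame(feature = f,
               min = suppressWarnings(min(v, na.rm = TRUE)),
               max = suppressWarnings(max(v, na.rm = TRUE)),
               mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE),
               median = median(v, na.rm = TRUE),
               fold_ip = mean(d$fold_ip, na.rm = TRUE),
               fold_ma = mean(d$fold_ma, na.rm = TRUE))
  }))
  lfold <- function(x) {
    out <- rep(NA_real_, length(x))
    ok <- is.finite(x) & x > 0
    out[ok] <- abs(log2(x[ok]))
    out
  }
  score <- pmax(lfold(agg$fold_ip), lfold(agg$fold_ma), na.rm = TRUE)
  score[!is.finite(score)] <- -Inf
  agg <- agg[order(-score), ]
  rownames(agg) <- NULL
  attr(agg, "per_cell") <- per_cell
  if (!is.null(out_dir)) .write_html_report(project, names(cells), agg, out_dir)
  agg
}

# Static single-directory HTML report: ranked table + one aligned mean-curve
# PNG per feature. No styling beyond a minimal embedded sheet, no JS.
.write_html_report <- function(project, ids, table, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  imgs <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    f <- table$feature[i]
    img <- sprintf("feature_%03d.png", i)
    ok <- try(render_plot(project, feature = f, kind = "mean_sd", ids = ids,
                          file = file.path(out_dir, img)), silent = TRUE)
    imgs[i] <- if (inherits(ok, "try-error")) NA_character_ else img
  }
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", as.character(x)))
  rows <- vapply(seq_len(nrow(table)), function(i) {
    cells <- vapply(names(table), function(cn) {
      v <- table[[cn]][i]
      if (is.numeric(v)) sprintf("%.4g", v) else esc(v)
    }, "")
    img <- if (!is.na(imgs[i]))
      sprintf('<br/><img src="%s" width="480"/>', imgs[i]) else ""
    paste0("<tr><td>", paste(cells, collapse = "</td><td>"), img,
           "</td></tr>")
  }, "")
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>Feature ranking</title>",
            "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:4px}</style>",
            "</head><body>",
            sprintf("<h1>Ranked feature fold changes (%d cells)</h1>",
                    length(ids)),
            "<table><tr><th>",
            paste(names(table), collapse = "</th><th>"), "</th></tr>",
            rows, "</table></body></html>")
  writeLines(html, file.path(out_dir, "index.html"))
  invisible(file.path(out_dir, "index.html"))
}

#' Statistical tests of a single feature across groups
#'
#' Parametric (two-sample t-test, one-way ANOVA) and non-parametric
#' (Wilcoxon rank-sum, Kruskal-Wallis) comparisons of per-cell single-feature
#' values between groups. Two-group tests require exactly two groups; groups
#' with fewer than 2 values are excluded with a warning.
#'
#' @param values_by_group named list of numeric vectors.
#' @param test `"t_test"`, `"anova"`, `"wilcoxon"` or `"kruskal_wallis"`.
#' @return one-row data.frame: test, statistic, p, and `n_<group>` columns.
#' @export
run_single_feature_tests <- function(values_by_group,
                                     test = c("t_test", "anova", "wilcoxon",
                                              "kruskal_wallis")) {
  test <- match.arg(test)
  values_by_group <- lapply(values_by_group, function(v) v[!is.na(v)])
  small <- vapply(values_by_group, length, 0L) < 2L
  if (any(small)) {
    warning("excluding group(s) with n < 2: ",
            paste(names(values_by_group)[small], collapse = ", "))
    values_by_group <- values_by_group[!small]
  }
  k <- length(values_by_group)
  if (k < 2L) stop_mitotraj("need at least 2 groups with n >= 2")
  if (test %in% c("t_test", "wilcoxon") && k != 2L)
    stop_mitotraj(test, " requires exactly 2 groups (got ", k, ")")
  g <- factor(rep(names(values_by_group),
                  vapply(values_by_group, length, 0L)),
              levels = names(values_by_group))
  v <- unlist(values_by_group, use.names = FALSE)
  res <- switch(test,
    t_test = {
      r <- t.test(values_by_group[[1]], values_by_group[[2]])
      c(statistic = unname(r$statistic), p = r$p.value)
    },
    wilcoxon = {
      r <- suppressWarnings(wilcox.test(values_by_group[[1]],
                                        values_by_group[[2]]))
      c(statistic = unname(r$statistic), p = r$p.value)
    },
    anova = {
      a <- summary(aov(v ~ g))[[1]]
      c(statistic = a[["F value"]][1], p = a[["Pr(>F)"]][1])
    },
    kruskal_wallis = {
      r <- kruskal.test(v, g)
      c(statistic = unname(r$statistic), p = r$p.value)
    })
  out <- data.frame(test = test, statistic = res["statistic"], p = res["p"])
  for (nm in names(values_by_group))
    out[[paste0("n_", nm)]] <- length(values_by_group[[nm]])
  rownames(out) <- NULL
  out
}

#' Test many single features at once, with multiplicity adjustment
#'
#' Runs [run_single_feature_tests()] per feature and reports the raw
#' p-values next to Benjamini-Hochberg adjusted ones, in a
#' spreadsheet-exportable table.
#'
#' @param project a [cell_project()].
#' @param ids_by_group named list of cell-id vectors.
#' @param features single-feature names (default: all).
#' @param test test name, see [run_single_feature_tests()].
#' @return data.frame: feature, statistic, p, p_adj, group sizes.
#' @export
feature_test_table <- function(project, ids_by_group, features = NULL,
                               test = "t_test") {
  features <- features %||% project$single_features
  rows <- lapply(features, function(f) {
    vals <- lapply(ids_by_group, function(ids)
      vapply(project$cells[ids], function(cell) cell$single[[f]], 0))
    r <- try(suppressWarnings(run_single_feature_tests(vals, test)),
             silent = TRUE)
    if (inherits(r, "try-error")) {
      r <- data.frame(test = test, statistic = NA_real_, p = NA_real_)
      for (nm in names(vals)) r[[paste0("n_", nm)]] <- length(vals[[nm]])
    }
    cbind(feature = f, r)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Two-way (treatment x time) ANOVA on aligned time series
#'
#' Each cell's series is mapped onto the common [aligned_time_axis()] and the
#' IP-to-MA block resampled onto a fixed number of bins, then a two-way ANOVA
#' with factors treatment (group), time (axis bin) and their interaction is
#' fitted on the long-format layout. Groups must all contribute values to
#' every used time bin.
#'
#' @param series_by_group named list; each element a numeric matrix
#'   (cells x aligned time bins), e.g. from [.aligned_feature_matrix()]
#'   via [run_timeseries_anova_project()].
#' @return data.frame with rows treatment, time, interaction: df, F, p.
#' @export
run_timeseries_anova <- function(series_by_group) {
  stopifnot(is.list(series_by_group), length(series_by_group) >= 2L)
  nb <- unique(vapply(series_by_group, ncol, 0L))
  if (length(nb) != 1L)
    stop_mitotraj("all groups must share the aligned axis length")
  long <- do.call(rbind, lapply(names(series_by_group), function(gn) {
    m <- series_by_group[[gn]]
    data.frame(group = gn,
               time = rep(seq_len(ncol(m)), each = nrow(m)),
               value = as.numeric(m))
  }))
  long <- long[!is.na(long$value), ]
  # every (group, time) cell must be populated
  tab <- table(long$group, long$time)
  if (any(tab == 0)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    stop_mitotraj("empty (group, time) cell(s): ",
                  paste(rownames(tab)[miss[, 1]], colnames(tab)[miss[, 2]],
                        sep = "@", collapse = ", "))
  }
  if (length(unique(long$time)) < 2L)
    stop_mitotraj("need at least 2 time points for a treatment x time ANOVA")
  long$group <- factor(long$group)
  long$time <- factor(long$time)
  a <- summary(aov(value ~ group * time, data = long))[[1]]
  data.frame(factor = c("treatment", "time", "interaction"),
             df = a$Df[1:3], F = a[["F value"]][1:3], p = a[["Pr(>F)"]][1:3])
}

#' Aligned time-series ANOVA straight from a project
#'
#' @param project a [cell_project()].
#' @param ids_by_group named list of cell-id vectors.
#' @param feature time-series feature name.
#' @param n_bins bins for the IP-to-MA block (default 10).
#' @return see [run_timeseries_anova()].
#' @export
run_timeseries_anova_project <- function(project, ids_by_group, feature,
                                         n_bins = 10L) {
  syncs <- unlist(lapply(unlist(ids_by_group), function(id)
    list(project$cells[[id]]$sync)), recursive = FALSE)
  axis <- aligned_time_axis(syncs, n_mid = n_bins)
  mats <- lapply(ids_by_group, function(ids)
    .aligned_feature_matrix(project, ids, feature, axis)$matrix)
  run_timeseries_anova(mats)
}

#' Render one of the standard plot kinds to a PNG file
#'
#' Temporal kinds (`heatmap`, `mean_sd`, `combined_lines`) draw on the
#' aligned three-segment time axis with vertical anchor lines at the IP and
#' MA transitions and require synchronized cells; distribution kinds
#' (`violin`, `box`, `histogram`) draw per-cell single-feature values.
#' Grouping: `ids` pools all cells in one panel; `ids_by_group` draws one
#' panel per group (`mean_sd`, distribution kinds) or one line per group in
#' a shared axis (`combined_lines`).
#'
#' @param project a [cell_project()].
#' @param feature a time-series feature (temporal kinds) or single feature
#'   (distribution kinds).
#' @param kind plot kind.
#' @param ids pooled cell ids (temporal kinds; default all synchronized).
#' @param ids_by_group named list of id vectors for grouped kinds.
#' @param file output PNG path.
#' @param n_mid IP-to-MA axis slots (default from the data).
#' @return invisibly, a list with `file`, and for temporal kinds `data` (the
#'   aligned matrix or matrices) and `anchors` (IP/MA axis positions).
#' @export
render_plot <- function(project, feature,
                        kind = c("heatmap", "mean_sd", "combined_lines",
                                 "violin", "box", "histogram"),
                        ids = NULL, ids_by_group = NULL, file,
                        n_mid = NULL) {
  kind <- match.arg(kind)
  temporal <- kind %in% c("heatmap", "mean_sd", "combined_lines")
  groups <- ids_by_group %||% list(all = ids %||% names(project$cells))
  if (temporal) {
    syncs <- lapply(unlist(groups), function(id) project$cells[[id]]$sync)
    axis <- aligned_time_axis(syncs, n_mid = n_mid)
    mats <- lapply(groups, function(g)
      .aligned_feature_matrix(project, g, feature, axis)$matrix)
  } else {
    vals <- lapply(groups, function(g)
      vapply(project$cells[g], function(cell) cell$single[[feature]], 0))
  }
  png(file, width = 900, height = if (length(groups) > 1) 320 * length(groups)
      else 480, res = 96)
  on.exit(dev.off(), add = TRUE)
  anchors <- NULL
  if (temporal) {
    anchors <- c(ip = axis$ip_pos, ma = axis$ma_pos)
    if (kind == "heatmap") {
      m <- do.call(rbind, mats)
      image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
            col = hcl.colors(64, "viridis"), xlab = "aligned frame",
            ylab = "cell", main = feature, useRaster = TRUE)
      abline(v = anchors - 0.5, col = "white", lwd = 2, lty = 2)
    } else if (kind == "mean_sd") {
      par(mfrow = c(length(mats), 1), mar = c(4, 4, 2, 1))
      for (gn in names(mats)) {
        m <- mats[[gn]]
        mu <- colMeans(m, na.rm = TRUE)
        s <- apply(m, 2, sd, na.rm = TRUE)
        xs <- seq_along(mu)
        plot(xs, mu, type = "n", xlab = "aligned frame", ylab = feature,
             main = paste(feature, "-", gn),
             ylim = range(c(mu - s, mu + s), na.rm = TRUE, finite = TRUE))
        ok <- is.finite(mu) & is.finite(s)
        polygon(c(xs[ok], rev(xs[ok])), c((mu - s)[ok], rev((mu + s)[ok])),
                col = adjustcolor("steelblue", 0.3), border = NA)
        lines(xs, mu, col = "steelblue4", lwd = 2)
        abline(v = anchors, lty = 2, col = "gray40")
      }
    } else {                                   # combined_lines
      cols <- hcl.colors(max(3L, length(mats)), "Dark 3")
      mus <- lapply(mats, colMeans, na.rm = TRUE)
      plot(NULL, xlim = c(1, axis$length),
           ylim = range(unlist(mus), na.rm = TRUE, finite = TRUE),
           xlab = "aligned frame", ylab = feature, main = feature)
      for (i in seq_along(mus))
        lines(seq_along(mus[[i]]), mus[[i]], col = cols[i], lwd = 2)
      abline(v = anchors, lty = 2, col = "gray40")
      legend("topright", legend = names(mats), col = cols[seq_along(mus)],
             lwd = 2, bty = "n")
    }
  } else if (kind == "box") {
    boxplot(vals, main = feature, ylab = feature)
  } else if (kind == "histogram") {
    par(mfrow = c(length(vals), 1), mar = c(4, 4, 2, 1))
    for (gn in names(vals))
      hist(vals[[gn]], main = paste(feature, "-", gn), xlab = feature,
           col = "steelblue", border = "white")
  } else {                                     # violin via kernel densities
    plot(NULL, xlim = c(0.5, length(vals) + 0.5),
         ylim = range(unlist(vals), na.rm = TRUE, finite = TRUE),
         xaxt = "n", xlab = "", ylab = feature, main = feature)
    axis(1, at = seq_along(vals), labels = names(vals))
    for (i in seq_along(vals)) {
      v <- vals[[i]][is.finite(vals[[i]])]
      if (length(v) >= 2 && sd(v) > 0) {
        d <- density(v)
        w <- 0.4 * d$y / max(d$y)
        polygon(c(i - w, rev(i + w)), c(d$x, rev(d$x)),
                col = adjustcolor("steelblue", 0.5), border = "steelblue4")
      }
      points(rep(i, length(v)) + runif(length(v), -0.05, 0.05), v, pch = 16,
             cex = 0.4, col = adjustcolor("black", 0.4))
      segments(i - 0.2, median(v), i + 0.2, median(v), lwd = 2)
    }
  }
  invisible(list(file = file,
                 data = if (temporal) mats else vals,
                 anchors = anchors))
}
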