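# Factorial experiment runner (designs x diameters x plaque modes x
# geometry seeds), group statistics (normality-gated ANOVA/Bonferroni or
# Friedman/Dunn) and report generation.

#' Factorial design of the stent comparison experiment
#'
#' The defaults are the study conditions: the four catalog designs, three
#' balloon sizing diameters, the five homogeneous plaque categories plus
#' heterogeneous zoning, and four vessel geometry seeds.
#'
#' @param designs Subset of [stent_catalog_names()].
#' @param diameters Balloon sizing diameters in mm.
#' @param plaque_modes Subset of `c(plaque_categories(), "heterogeneous")`.
#' @param seeds Integer vessel geometry seeds (the replicates; SEM is taken
#'   across these).
#' @return An object of class `factorial_design`.
#' @export
factorial_design <- function(designs = stent_catalog_names(),
                             diameters = c(3.5, 4.5, 5.0),
                             plaque_modes = c(plaque_categories(),
                                              "heterogeneous"),
                             seeds = 1:4) {
  stopifnot(length(designs) > 0, length(diameters) > 0,
            length(plaque_modes) > 0, length(seeds) > 0,
            all(diameters > 0))
  bad <- setdiff(designs, stent_catalog_names())
  if (length(bad) > 0) stop("unknown design(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(plaque_modes, c(plaque_categories(), "heterogeneous"))
  if (length(bad) > 0) stop("unknown plaque mode(s): ",
                            paste(bad, collapse = ", "))
  fd <- list(designs = designs, diameters = diameters,
             plaque_modes = plaque_modes, seeds = as.integer(seeds))
  class(fd) <- "factorial_design"
  fd
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf(
    "<factorial_design> %d designs x %d diameters x %d plaque modes x %d seeds = %d cells\n",
    length(x$designs), length(x$diameters), length(x$plaque_modes),
    length(x$seeds),
    length(x$designs) * length(x$diameters) * length(x$plaque_modes) *
      length(x$seeds)))
  invisible(x)
}

# vessel for one (seed, plaque mode)
.factorial_vessel <- function(seed, plaque_mode) {
  v <- generate_bifurcation(seed = seed)
  if (plaque_mode == "heterogeneous") {
    assign_heterogeneous_plaque(v, seed = seed)
  } else {
    assign_homogeneous_plaque(v, plaque_mode)
  }
}

#' Run the factorial stent comparison experiment
#'
#' For each cell, a seeded bifurcation vessel is generated, the given
#' plaque mode is assigned, the design's lattice is expanded to the cell's
#' sizing diameter at the configured pressure and recoiled, and the full
#' metrics row is computed. The normalized hoop force comes from one
#' simulated crimp test per (design, diameter), shared across vessels as
#' in the bench protocol. Failed cells are logged, never silently dropped.
#'
#' @param fd A [factorial_design()].
#' @param config A [solver_config()]; its `target_diameter` is overridden
#'   per cell by the factorial diameter.
#' @param verbose Print one line per cell.
#' @return A tibble (the results table) with one metrics row per completed
#'   cell plus the factor columns `design`, `diameter`, `plaque`, `seed`.
#'   Attributes: `failures` (tibble of failed cells with error messages),
#'   `attempted`, `completed`.
#' @export
run_factorial <- function(fd, config = solver_config(), verbose = FALSE) {
  stopifnot(inherits(fd, "factorial_design"))
  rows <- list()
  failures <- list()
  crimps <- list()
  lattices <- list()
  attempted <- 0L
  for (dn in fd$designs) {
    design <- stent_catalog(dn)
    lattices[[dn]] <- build_lattice(design)
    for (dia in fd$diameters) {
      key <- sprintf("%s|%.2f", dn, dia)
      crimps[[key]] <- radial_crimp(design, diameter = dia,
                                    alloy = config$alloy)
    }
  }
  for (seed in fd$seeds) {
    for (pm in fd$plaque_modes) {
      vessel <- .factorial_vessel(seed, pm)
      for (dn in fd$designs) {
        design <- stent_catalog(dn)
        for (dia in fd$diameters) {
          attempted <- attempted + 1L
          cfg <- config
          cfg$target_diameter <- dia
          meta <- list(design = dn, diameter = dia, plaque = pm,
                       seed = as.integer(seed))
          res <- tryCatch({
            state <- expand_stent(lattices[[dn]], design, vessel,
                                  config = cfg)
            metrics_report(state, crimps[[sprintf("%s|%.2f", dn, dia)]],
                           metadata = meta)
          }, error = function(e) e)
          if (inherits(res, "error")) {
            failures[[length(failures) + 1L]] <- tibble::tibble(
              design = dn, diameter = dia, plaque = pm,
              seed = as.integer(seed), error = conditionMessage(res))
            if (verbose) {
              message(sprintf("FAIL %s d=%.1f %s seed=%d: %s", dn, dia, pm,
                              seed, conditionMessage(res)))
            }
          } else {
            rows[[length(rows) + 1L]] <- res
            if (verbose) {
              message(sprintf("ok   %s d=%.1f %s seed=%d msd=%.3f", dn, dia,
                              pm, seed, res$msd))
            }
          }
        }
      }
    }
  }
  tab <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble::tibble()
  attr(tab, "failures") <- if (length(failures) > 0) {
    dplyr::bind_rows(failures)
  } else {
    tibble::tibble(design = character(), diameter = numeric(),
                   plaque = character(), seed = integer(),
                   error = character())
  }
  attr(tab, "attempted") <- attempted
  attr(tab, "completed") <- length(rows)
  tab
}

.sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(0)
  stats::sd(x) / sqrt(length(x))
}

#' Percentage expansion difference between two designs
#'
#' For each (diameter, plaque mode, seed) block, the percentage difference
#' `(a - reference) / reference * 100` of the chosen metric between the
#' two designs, then mean and SEM across seeds per (diameter, plaque).
#'
#' @param table A [run_factorial()] results table.
#' @param design_a,design_b The two design names.
#' @param reference Reference design for the denominator (default
#'   `design_b`, the convention of reporting against the sparser design).
#' @param metric Metric column (default `"msd"`).
#' @return A tibble with columns `diameter`, `plaque`, `mean_pct_diff`,
#'   `sem_pct_diff`, `n_seeds`.
#' @export
expansion_difference <- function(table, design_a, design_b,
                                 reference = design_b, metric = "msd") {
  stopifnot(metric %in% names(table))
  stopifnot(reference %in% c(design_a, design_b))
  for (dn in c(design_a, design_b)) {
    if (!dn %in% table$design) stop(sprintf("design '%s' not in table", dn))
  }
  sub <- table[table$design %in% c(design_a, design_b),
               c("design", "diameter", "plaque", "seed", metric)]
  wide <- tidyr::pivot_wider(sub, names_from = "design",
                             values_from = dplyr::all_of(metric))
  miss <- wide[is.na(wide[[design_a]]) | is.na(wide[[design_b]]), ]
  if (nrow(miss) > 0) {
    stop("missing cells for: ",
         paste(sprintf("(d=%.1f, %s, seed %d)", miss$diameter, miss$plaque,
                       miss$seed), collapse = "; "))
  }
  wide$pct_diff <- (wide[[design_a]] - wide[[design_b]]) /
    wide[[reference]] * 100
  out <- dplyr::summarise(
    dplyr::group_by(wide, .data$diameter, .data$plaque),
    mean_pct_diff = mean(.data$pct_diff),
    sem_pct_diff = .sem(.data$pct_diff),
    n_seeds = dplyr::n(), .groups = "drop")
  attr(out, "design_a") <- design_a
  attr(out, "design_b") <- design_b
  attr(out, "reference") <- reference
  out
}

# Dunn's posthoc test after Friedman: pairwise z statistics on within-block
# rank sums, two-sided normal p-values, Bonferroni-adjusted
.dunn_posthoc <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  ranks <- t(apply(mat, 1, rank))
  rsum <- colSums(ranks)
  se <- sqrt(n * k * (k + 1) / 6)
  pairs <- utils::combn(k, 2)
  z <- abs(rsum[pairs[1, ]] - rsum[pairs[2, ]]) / se
  p <- 2 * stats::pnorm(-z)
  tibble::tibble(
    group1 = colnames(mat)[pairs[1, ]],
    group2 = colnames(mat)[pairs[2, ]],
    z = z,
    p_value = p,
    p_adjusted = pmin(p * ncol(pairs), 1)
  )
}

#' Compare metric distributions between groups
#'
#' Group observations are the per-(group, block) means of the chosen
#' metric (blocks default to geometry seeds, the experimental replicates).
#' A Kolmogorov-Smirnov test on the standardized within-group residuals
#' gates the branch: one-way analysis of variance with Bonferroni-adjusted
#' pairwise t-tests if normality is not rejected at 0.05, otherwise the
#' Friedman rank test on complete blocks with Dunn's Bonferroni-adjusted
#' posthoc. Both branches are always computed and returned. Identical
#' groups (zero spread everywhere) yield adjusted p = 1 by convention.
#'
#' @param table A [run_factorial()] results table (or any tibble with the
#'   metric, grouping and block columns).
#' @param metric Metric column name.
#' @param grouping Grouping column (default `"design"`).
#' @param block Blocking column for Friedman pairing (default `"seed"`).
#' @return A list of class `group_comparison`: `method` (chosen branch),
#'   `normality_p`, `anova` (F statistic, p, pairwise tibble), `friedman`
#'   (chi-squared statistic, p, Dunn tibble, `n_blocks_dropped`), `data`.
#' @export
compare_groups <- function(table, metric, grouping = "design",
                           block = "seed") {
  stopifnot(metric %in% names(table), grouping %in% names(table),
            block %in% names(table))
  df <- tibble::tibble(group = as.character(table[[grouping]]),
                       block = table[[block]],
                       value = table[[metric]])
  df <- df[!is.na(df$value), ]
  agg <- dplyr::summarise(dplyr::group_by(df, .data$group, .data$block),
                          value = mean(.data$value), .groups = "drop")
  groups <- sort(unique(agg$group))
  if (length(groups) < 2) stop("need at least 2 groups")
  n_per <- table(agg$group)
  if (any(n_per < 3)) stop("need at least 3 observations per group")

  gmeans <- tapply(agg$value, agg$group, mean)
  resid <- agg$value - gmeans[agg$group]
  identical_groups <- stats::var(agg$value) < 1e-24 ||
    all(abs(gmeans - mean(agg$value)) < 1e-12) && stats::sd(resid) < 1e-12

  if (stats::sd(resid) > 1e-12) {
    ks <- suppressWarnings(
      stats::ks.test(resid / stats::sd(resid), "pnorm"))
    normality_p <- ks$p.value
  } else {
    normality_p <- 1  # degenerate residuals: nothing to reject
  }

  pairs <- utils::combn(length(groups), 2)
  pair_tbl <- tibble::tibble(group1 = groups[pairs[1, ]],
                             group2 = groups[pairs[2, ]])

  if (stats::var(agg$value) < 1e-24) {
    # identical observations everywhere: no evidence of any difference
    anova_res <- list(statistic = 0, p_value = 1,
                      pairwise = dplyr::mutate(pair_tbl, p_adjusted = 1))
    fried_res <- list(statistic = 0, p_value = 1,
                      pairwise = dplyr::mutate(pair_tbl, z = 0,
                                               p_value = 1, p_adjusted = 1),
                      n_blocks_dropped = 0L)
  } else {
    fit <- stats::aov(value ~ group, data = agg)
    sm <- summary(fit)[[1]]
    pw <- stats::pairwise.t.test(agg$value, agg$group,
                                 p.adjust.method = "bonferroni")
    p_adj <- vapply(seq_len(ncol(pairs)), function(j) {
      g1 <- groups[pairs[1, j]]; g2 <- groups[pairs[2, j]]
      v <- pw$p.value[g2, g1]
      if (is.na(v) && g1 %in% rownames(pw$p.value)) v <- pw$p.value[g1, g2]
      v
    }, 1)
    p_adj[is.na(p_adj)] <- 1
    anova_res <- list(statistic = sm[["F value"]][1],
                      p_value = sm[["Pr(>F)"]][1],
                      pairwise = dplyr::mutate(pair_tbl,
                                               p_adjusted = p_adj))
    wide <- tidyr::pivot_wider(agg, names_from = "group",
                               values_from = "value")
    mat <- as.matrix(wide[, groups, drop = FALSE])
    complete <- stats::complete.cases(mat)
    dropped <- sum(!complete)
    mat <- mat[complete, , drop = FALSE]
    if (nrow(mat) >= 2) {
      fr <- stats::friedman.test(mat)
      fried_res <- list(statistic = unname(fr$statistic),
                        p_value = fr$p.value,
                        pairwise = .dunn_posthoc(mat),
                        n_blocks_dropped = dropped)
    } else {
      fried_res <- list(statistic = NA_real_, p_value = NA_real_,
                        pairwise = dplyr::mutate(pair_tbl, z = NA_real_,
                                                 p_value = NA_real_,
                                                 p_adjusted = NA_real_),
                        n_blocks_dropped = dropped)
    }
  }

  out <- list(
    method = if (normality_p > 0.05) "anova" else "friedman",
    normality_p = normality_p,
    anova = anova_res,
    friedman = fried_res,
    groups = groups,
    data = agg
  )
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  chosen <- if (x$method == "anova") x$anova else x$friedman
  cat(sprintf(
    "<group_comparison> %d groups, branch '%s' (KS normality p = %.3f): statistic %.3f, p = %.4g\n",
    length(x$groups), x$method, x$normality_p, chosen$statistic,
    chosen$p_value))
  invisible(x)
}

#' Grouped summary report of a factorial results table
#'
#' For each metric, group means and SEMs across geometry seeds per
#' (design, diameter, plaque) cell, written as one CSV per metric
#' (deterministic row and column order, so regeneration is
#' byte-identical) and optionally one grouped bar figure per metric.
#'
#' @param table A [run_factorial()] results table.
#' @param out_dir Output directory (created if needed); `NULL` returns the
#'   summaries without writing.
#' @param metrics Metric columns to summarize.
#' @param plots Also write `<metric>.pdf` bar charts (requires `out_dir`).
#' @return Named list of summary tibbles, invisibly if written.
#' @export
make_report <- function(table, out_dir = NULL,
                        metrics = c("msd", "ccd", "prolapse", "sar",
                                    "hoop_force", "radial_strength"),
                        plots = FALSE) {
  metrics <- intersect(metrics, names(table))
  summaries <- list()
  for (m in metrics) {
    if (nrow(table) == 0) {
      s <- tibble::tibble(design = character(), diameter = numeric(),
                          plaque = character(), mean = numeric(),
                          sem = numeric(), n = integer())
    } else {
      s <- dplyr::summarise(
        dplyr::group_by(table, .data$design, .data$diameter, .data$plaque),
        mean = mean(.data[[m]], na.rm = TRUE),
        sem = .sem(.data[[m]]),
        n = sum(!is.na(.data[[m]])), .groups = "drop")
      s <- dplyr::arrange(s, .data$design, .data$diameter, .data$plaque)
    }
    summaries[[m]] <- s
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      readr::write_csv(s, file.path(out_dir, paste0(m, "_summary.csv")))
      if (plots && nrow(s) > 0) {
        gg <- ggplot2::ggplot(
          s, ggplot2::aes(x = .data$design, y = .data$mean,
                          fill = factor(.data$diameter))) +
          ggplot2::geom_col(position = "dodge") +
          ggplot2::geom_errorbar(
            ggplot2::aes(ymin = .data$mean - .data$sem,
                         ymax = .data$mean + .data$sem),
            position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
          ggplot2::facet_wrap(~plaque) +
          ggplot2::labs(x = NULL, y = m, fill = "diameter (mm)") +
          ggplot2::theme_minimal(base_size = 9) +
          ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                             hjust = 1))
        ggplot2::ggsave(file.path(out_dir, paste0(m, ".pdf")), gg,
                        width = 8, height = 6)
      }
    }
  }
  if (is.null(out_dir)) summaries else invisible(summaries)
}

#' Write a factorial results table as CSV
#'
#' Deterministic column order; reruns with identical seeds are
#' byte-identical.
#'
#' @param table A [run_factorial()] results table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(table, path) {
  first <- intersect(c("design", "diameter", "plaque", "seed"), names(table))
  tab <- table[, c(first, setdiff(names(table), first))]
  readr::write_csv(tab, path)
  invisible(path)
}
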