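#' Signed maximum difference between two curves
#'
#' The element of `y_pre - y` with the largest magnitude, sign retained.
#' Ties are broken toward the higher (later, higher-pressure) index.
#'
#' @param y_pre Predicted series (membrane model).
#' @param y Reference series (in silico model).
#' @return Signed scalar in the units of the inputs.
#' @export
#' @examples
#' delta_max(c(1, 2, 3), c(1, 1, 1)) # 2
delta_max <- function(y_pre, y) {
  stopifnot(length(y_pre) == length(y), length(y) > 0)
  d <- y_pre - y
  d[max(which(abs(d) == max(abs(d))))]
}

#' Offset-corrected coefficient of determination
#'
#' `R^2 = 1 - sum((delta - mean(delta))^2) / sum((y - mean(y))^2)` with
#' `delta = y_pre - y`: the mean offset between the curves is removed before
#' scoring, so only the shape agreement is quantified (the offset is reported
#' separately by [delta_max()]). Negative values indicate a complete lack of
#' shape agreement and are clipped to zero. If the reference curve is
#' constant the measure is undefined and `NA` is returned.
#'
#' @inheritParams delta_max
#' @return Value in `[0, 1]`, or `NA_real_` for a constant reference.
#' @export
r_hat_squared <- function(y_pre, y) {
  stopifnot(length(y_pre) == length(y), length(y) > 1)
  den <- sum((y - mean(y))^2)
  if (den < max(.Machine$double.eps, 1e-18 * length(y) * mean(y)^2)) {
    return(NA_real_)
  }
  d <- y_pre - y
  val <- 1 - sum((d - mean(d))^2) / den
  max(val, 0)
}

#' Compare membrane predictions with one in silico aorta
#'
#' Runs the full single-set evaluation: sweeps the thick-walled model over
#' the pressure grid, evaluates its mid-wall stress state and through-wall
#' load fractions per level, evaluates the constitutive membrane stresses at
#' the given parameters on the simulated `(P, ri, h)` signal, and scores
#' every component (isotropic, anisotropic, total stress in both directions,
#' the load-bearing fractions, and the reaction stress) by the signed
#' maximum difference and the offset-corrected coefficient of determination.
#'
#' @param artery One row of [silico_aortas()].
#' @param params One row of [membrane_parameters()], or the `params` of an
#'   [identify_parameters()] fit.
#' @param config A [run_config()].
#' @param silico Optional precomputed [midwall_stress_series()] for the same
#'   artery/config (avoids re-solving).
#' @return A tibble of class `aorta_comparison` with columns `direction`
#'   (`theta`, `z`, `radial`), `component` (`iso`, `aniso`, `total`,
#'   `fraction`, `reaction`), `delta_max`, `r_hat_sq`. The per-level series
#'   of both models are attached as attribute `"series"` (rows stacked with
#'   a `model` column).
#' @export
compare_set <- function(artery, params, config = run_config(), silico = NULL) {
  if (is.null(silico)) silico <- midwall_stress_series(artery, config)
  mem <- membrane_stress_series(silico[c("P", "ri", "h")], params)
  pair <- function(direction, component, pre, ref) {
    tibble(direction = direction, component = component,
           delta_max = delta_max(pre, ref),
           r_hat_sq = r_hat_squared(pre, ref))
  }
  out <- dplyr::bind_rows(
    pair("theta", "iso", mem$sigma_iso_theta, silico$sigma_iso_theta),
    pair("theta", "aniso", mem$sigma_aniso_theta, silico$sigma_aniso_theta),
    pair("theta", "total", mem$sigma_total_theta, silico$sigma_total_theta),
    pair("theta", "fraction", mem$psi_theta, silico$psi_theta),
    pair("z", "iso", mem$sigma_iso_z, silico$sigma_iso_z),
    pair("z", "aniso", mem$sigma_aniso_z, silico$sigma_aniso_z),
    pair("z", "total", mem$sigma_total_z, silico$sigma_total_z),
    pair("z", "fraction", mem$psi_z, silico$psi_z),
    pair("radial", "reaction", mem$reaction_p, silico$reaction_p)
  )
  class(out) <- c("aorta_comparison", class(out))
  attr(out, "series") <- dplyr::bind_rows(silico, mem)
  out
}

#' Evaluate all parameter sets
#'
#' Runs [compare_set()] for every in silico aorta. In `"fixture"` mode the
#' packaged identified parameters are used as-is (fully deterministic). In
#' `"reidentify"` mode the membrane parameters are re-identified from each
#' simulated series by [identify_parameters()] before scoring, which mirrors
#' the original procedure end to end; the tabulated identified parameters are
#' printed rounded, and the membrane stresses are sensitive enough to the
#' unloaded radius that only re-identification reproduces the published
#' per-set metrics.
#'
#' @param arteries Rows of [silico_aortas()].
#' @param params Matching rows of [membrane_parameters()] (fixture/refit
#'   modes).
#' @param config A [run_config()].
#' @param mode `"fixture"`, `"refit"` (deterministic refinement of the
#'   packaged parameters, see [refit_membrane_parameters()]) or
#'   `"reidentify"`.
#' @param seed Seed for the identification starts (reidentify mode).
#' @param n_starts Starts per set (reidentify mode).
#' @return Tibble with columns `set`, `group`, `direction`, `component`,
#'   `delta_max`, `r_hat_sq`; the per-set identified parameters (refit and
#'   reidentify modes) are attached as attribute `"identified"`, the per-set
#'   mid-wall series as attribute `"series"`.
#' @export
evaluate_sets <- function(arteries = silico_aortas(),
                          params = membrane_parameters(),
                          config = run_config(),
                          mode = c("fixture", "refit", "reidentify"),
                          seed = 1, n_starts = 64) {
  mode <- match.arg(mode)
  stopifnot(nrow(arteries) >= 1)
  idx <- seq_len(nrow(arteries))
  identified <- vector("list", length(idx))
  series_list <- vector("list", length(idx))
  rows <- purrr::map(idx, function(i) {
    art <- arteries[i, ]
    silico <- midwall_stress_series(art, config)
    series_list[[i]] <<- silico
    if (mode == "fixture") {
      pp <- params[params$set == art$set, ]
      stopifnot(nrow(pp) == 1)
    } else {
      fit <- if (mode == "refit") {
        pp0 <- params[params$set == art$set, ]
        stopifnot(nrow(pp0) == 1)
        f <- refit_membrane_parameters(silico[c("P", "ri", "h")], pp0, config)
        # thin-wall admissibility: the membrane reaction stress is provably
        # underpredicted relative to the thick wall near the true solution;
        # candidates violating that sit in spurious basins of the
        # overparameterized objective
        adm <- vapply(f$candidates, function(cd) {
          mem <- membrane_stress_series(silico[c("P", "ri", "h")],
                                        as.list(cd$par))
          delta_max(mem$reaction_p, silico$reaction_p) <= 1e-6
        }, logical(1))
        pool <- if (any(adm)) f$candidates[adm] else f$candidates[1]
        best <- pool[[which.min(vapply(pool, `[[`, numeric(1), "objective"))]]
        f$params <- as_tibble(as.list(best$par))
        f$objective <- best$objective
        f
      } else {
        identify_parameters(silico[c("P", "ri", "h")], config,
                            seed = seed + art$set, n_starts = n_starts)
      }
      pp <- fit$params
      identified[[i]] <<- dplyr::mutate(
        dplyr::bind_cols(tibble(set = art$set, group = art$group), pp),
        objective = fit$objective, fred_est = fit$fred_est
      )
    }
    cmp <- compare_set(art, pp, config, silico = silico)
    dplyr::bind_cols(tibble(set = art$set, group = art$group), cmp)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "identified") <- if (mode != "fixture") {
    dplyr::bind_rows(identified)
  }
  attr(out, "series") <- setNames(series_list, arteries$set)
  attr(out, "mode") <- mode
  out
}

#' Transmural stress gradients with group summaries
#'
#' Computes the transmural total-stress gradient (outer minus inner wall) in
#' both directions for every artery at the given pressure, and summarizes by
#' group with the median and interquartile range.
#'
#' @param arteries Rows of [silico_aortas()].
#' @param config A [run_config()].
#' @param pressure Evaluation pressure \[kPa\]. Defaults to systolic.
#' @param quantile_type Quantile algorithm for the quartiles (default from
#'   `config`).
#' @return A list with `per_set` (tibble: `set`, `group`, `gradient_theta`,
#'   `gradient_z` \[kPa\]) and `summary` (tibble: per group and direction the
#'   median and quartiles).
#' @export
gradient_table <- function(arteries = silico_aortas(),
                           config = run_config(),
                           pressure = config$P_sbp,
                           quantile_type = config$quantile_type) {
  per_set <- purrr::map_dfr(seq_len(nrow(arteries)), function(i) {
    prof <- transmural_profile(arteries[i, ], pressure, config)
    tibble(set = arteries$set[i], group = arteries$group[i],
           gradient_theta = transmural_gradient(prof, "theta"),
           gradient_z = transmural_gradient(prof, "z"))
  })
  summary <- per_set %>%
    tidyr::pivot_longer(dplyr::starts_with("gradient_"),
                        names_to = "direction", names_prefix = "gradient_",
                        values_to = "gradient") %>%
    dplyr::group_by(.data$group, .data$direction) %>%
    dplyr::summarise(
      median = median(.data$gradient),
      q1 = quantile(.data$gradient, 0.25, type = quantile_type, names = FALSE),
      q3 = quantile(.data$gradient, 0.75, type = quantile_type, names = FALSE),
      .groups = "drop"
    )
  list(per_set = per_set, summary = summary)
}

#' Correlation of stress overprediction with the transmural gradient
#'
#' Pearson correlation, across parameter sets, between the circumferential
#' total-stress signed maximum difference and the magnitude of the
#' circumferential transmural stress gradient.
#'
#' @param metrics Output of [evaluate_sets()].
#' @param gradients `per_set` tibble of [gradient_table()].
#' @return A one-row tibble with `r`, `p_value`, `n`.
#' @export
correlation_delta_gradient <- function(metrics, gradients) {
  d <- metrics %>%
    dplyr::filter(.data$direction == "theta", .data$component == "total") %>%
    dplyr::select("set", "delta_max") %>%
    dplyr::inner_join(gradients, by = "set")
  if (nrow(d) < 3) stop("need at least 3 paired sets", call. = FALSE)
  ct <- cor.test(d$delta_max, abs(d$gradient_theta), method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(d))
}

#' Nonparametric comparison of the artery groups
#'
#' Kruskal--Wallis test across the groups at level `alpha`; when
#' significant, pairwise Mann--Whitney--Wilcoxon tests at the
#' Bonferroni-corrected level. A group is flagged as different only when it
#' differs significantly from *both* other groups; the highest of its
#' pairwise p-values is reported.
#'
#' @param values Numeric vector, one value per set.
#' @param groups Factor/character vector of group labels, same length.
#' @param alpha Significance level (default 0.05).
#' @return A list with `kruskal_p`, `pairwise` (tibble of pairwise p-values,
#'   `NULL` if the omnibus test is not significant), `flagged` (character
#'   vector of flagged groups) and `flagged_p` (named highest pairwise
#'   p-value per flagged group).
#' @export
group_tests <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need at least two groups with at least two members each",
         call. = FALSE)
  }
  kw <- kruskal.test(values, factor(groups))
  out <- list(kruskal_p = kw$p.value, pairwise = NULL,
              flagged = character(), flagged_p = numeric())
  if (is.na(kw$p.value) || kw$p.value >= alpha) return(out)
  pairs <- utils::combn(names(tab), 2, simplify = FALSE)
  level <- alpha / length(pairs)
  pw <- purrr::map_dfr(pairs, function(pr) {
    w <- suppressWarnings(
      wilcox.test(values[groups == pr[1]], values[groups == pr[2]],
                  exact = all(tab[pr] <= 8))
    )
    tibble(group1 = pr[1], group2 = pr[2], p_value = w$p.value,
           significant = w$p.value < level)
  })
  out$pairwise <- pw
  for (g in names(tab)) {
    mine <- pw[pw$group1 == g | pw$group2 == g, ]
    if (nrow(mine) == length(tab) - 1 && all(mine$significant)) {
      out$flagged <- c(out$flagged, g)
      out$flagged_p[g] <- max(mine$p_value)
    }
  }
  out
}

#' Consistency of the simulated reduced axial forces with the tabulated ones
#'
#' For every artery: the mean reduced axial force over the pressure sweep
#' (comparable to the tabulated `fred` of [silico_aortas()]) and the
#' gamma-ratio estimate from the geometry at MAP (comparable to the
#' tabulated `fred` of [membrane_parameters()]). The `fred_ok` flag marks
#' agreement of the sweep mean with the tabulated value within `tol_N`.
#'
#' @param arteries Rows of [silico_aortas()].
#' @param config A [run_config()].
#' @param series Optional named list of precomputed mid-wall series (as the
#'   `"series"` attribute of [evaluate_sets()]).
#' @param tol_N Agreement tolerance in newtons.
#' @return Tibble: `set`, `group`, `fred_mean`, `fred_tab`, `fred_ok`,
#'   `fred_est`, all forces in newtons.
#' @export
force_table <- function(arteries = silico_aortas(), config = run_config(),
                        series = NULL, tol_N = 0.02) {
  purrr::map_dfr(seq_len(nrow(arteries)), function(i) {
    art <- arteries[i, ]
    s <- if (!is.null(series)) series[[as.character(art$set)]]
    if (is.null(s)) s <- midwall_stress_series(art, config)
    ri_map <- approx(s$P, s$ri, config$P_map)$y
    h_map <- approx(s$P, s$h, config$P_map)$y
    fm <- mean(s$fred)
    tibble(set = art$set, group = art$group,
           fred_mean = fm, fred_tab = art$fred,
           fred_ok = is.finite(art$fred) && abs(fm - art$fred) <= tol_N,
           fred_est = estimate_reduced_force(ri_map, h_map, config))
  })
}
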