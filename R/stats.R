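#' Hierarchical permutation test for nested condition comparisons
#'
#' Distribution-free substitute for a nested ANOVA honoring the
#' animal/session hierarchy: condition labels are permuted at the session
#' level within each animal (sessions are the exchangeable units), the test
#' statistic is the difference of animal-level condition means (each animal
#' contributes equally), and the p-value is
#' \eqn{(1 + \#\{|T^*| \ge |T|\}) / (1 + n_{perm})}.
#'
#' @param data data.frame with a value column plus `condition`, `animal`,
#'   `session`.
#' @param value Name of the value column.
#' @param conditions Two condition labels to compare (default: the first
#'   two present).
#' @param n_perm Number of permutations (> 0).
#' @param seed Optional integer seed (bitwise-reproducible runs).
#' @param rank_based Apply a rank transform to the values first (makes the
#'   p-value invariant to monotone transforms).
#' @return A `"comparison_result"` list: `estimate` (condition mean
#'   difference on animal level), `p`, `n_animal`, `n_session`, `method`.
#' @export
hierarchical_permutation_test <- function(data, value = "value",
                                          conditions = NULL,
                                          n_perm = 1000L, seed = NULL,
                                          rank_based = FALSE) {
  stop_if(n_perm < 1L, "`n_perm` must be a positive number of permutations")
  need <- c(value, "condition", "animal", "session")
  stop_if(!all(need %in% names(data)),
          "data needs columns: ", paste(need, collapse = ", "))
  stop_if(anyNA(data[, need]), "observations must be fully labeled")
  if (is.null(conditions)) conditions <- unique(data$condition)[1:2]
  stop_if(length(conditions) != 2L || anyNA(conditions),
          "exactly two conditions required")
  d <- data[data$condition %in% conditions, , drop = FALSE]
  v <- d[[value]]
  if (rank_based) v <- rank(v)
  # exchangeable unit: the (animal, session, condition) cell mean; for
  # within-session state contrasts a session contributes one cell per
  # condition, for between-drug contrasts one cell total
  skey <- paste(d$animal, d$session, d$condition, sep = "\r")
  sm <- tapply(v, skey, mean)
  parts <- strsplit(names(sm), "\r")
  sanimal <- vapply(parts, `[[`, character(1), 1L)
  scond <- vapply(parts, `[[`, character(1), 3L)
  animals <- unique(sanimal)
  per_animal <- lapply(animals, function(a) {
    i <- sanimal == a
    list(vals = as.numeric(sm[i]), cond = as.character(scond[i]))
  })
  exch <- vapply(per_animal, function(pa)
    length(unique(pa$cond)) == 2L, logical(1))
  stop_if(!any(exch),
          paste("no animal holds sessions under both conditions;",
                "no exchangeable units exist for this design"))
  tstat <- function(assign_list) {
    d1 <- vapply(seq_along(per_animal), function(i) {
      pa <- per_animal[[i]]
      cond <- assign_list[[i]]
      m1 <- mean(pa$vals[cond == conditions[1L]])
      m2 <- mean(pa$vals[cond == conditions[2L]])
      m1 - m2
    }, numeric(1))
    mean(d1, na.rm = TRUE)
  }
  obs_assign <- lapply(per_animal, `[[`, "cond")
  t_obs <- tstat(obs_assign)
  if (!is.null(seed)) set.seed(seed)
  t_perm <- vapply(seq_len(n_perm), function(p) {
    tstat(lapply(per_animal, function(pa) sample(pa$cond)))
  }, numeric(1))
  p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
  structure(list(estimate = t_obs, p = p,
                 n_animal = length(animals), n_session = length(sm),
                 n_perm = n_perm,
                 method = if (rank_based)
                   "hierarchical permutation (rank)" else
                     "hierarchical permutation"),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: estimate %.4g, p = %.4g\n",
              x$method, x$estimate, x$p))
  invisible(x)
}

#' Wilcoxon rank-sum test on animal-level values
#'
#' Exact distribution for small untied samples, normal approximation
#' otherwise (the behavior of [stats::wilcox.test()]). Groups below `min_n`
#' are suppressed with a reason rather than tested.
#'
#' @param group_a,group_b Numeric vectors of animal-level values.
#' @param min_n Minimum group size (default 3).
#' @return A `"comparison_result"`: `estimate` (median difference), `p`,
#'   `method`; `p` is `NA` with a `reason` when suppressed.
#' @export
rank_sum_test <- function(group_a, group_b, min_n = 3L) {
  if (length(group_a) < min_n || length(group_b) < min_n) {
    return(structure(list(estimate = NA_real_, p = NA_real_,
                          method = "Wilcoxon rank sum",
                          reason = sprintf(
                            "group sizes %d and %d below minimum %d",
                            length(group_a), length(group_b), min_n)),
                     class = "comparison_result"))
  }
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b))
  structure(list(estimate = stats::median(group_a) - stats::median(group_b),
                 p = wt$p.value, statistic = unname(wt$statistic),
                 method = "Wilcoxon rank sum", reason = NA_character_),
            class = "comparison_result")
}

#' Kruskal-Wallis test across groups
#'
#' H statistic with tie correction and chi-square p-value via
#' [stats::kruskal.test()]. All-tied inputs degenerate to p = 1 with a
#' warning.
#'
#' @param groups List of numeric vectors (>= 2 groups, total n >= 5).
#' @return A `"comparison_result"`: `statistic` (H), `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stop_if(length(groups) < 2L, "need at least two groups")
  stop_if(sum(lengths(groups)) < 5L, "total sample size must be >= 5")
  allv <- unlist(groups)
  if (stats::var(allv) == 0) {
    warning("all values tied; test degenerate", call. = FALSE)
    return(structure(list(statistic = 0, df = length(groups) - 1L, p = 1,
                          method = "Kruskal-Wallis"),
                     class = "comparison_result"))
  }
  kt <- stats::kruskal.test(groups)
  structure(list(statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p = kt$p.value,
                 method = "Kruskal-Wallis"),
            class = "comparison_result")
}

#' Benjamini-Hochberg adjustment across structure-wise tests
#'
#' Convenience wrapper emitting raw and FDR-adjusted p-values for
#' significance maps across the recorded structures.
#'
#' @param p_values Named numeric vector of per-structure p-values.
#' @return data.frame with structure, p_raw, p_fdr.
#' @export
structure_fdr <- function(p_values) {
  data.frame(structure = names(p_values),
             p_raw = unname(p_values),
             p_fdr = stats::p.adjust(unname(p_values), method = "BH"),
             stringsAsFactors = FALSE)
}
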