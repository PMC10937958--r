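#' Build a global brain-state vector
#'
#' Concatenates per-structure time-averaged rhythmic-residue spectra
#' (dB_fractal, 1-300 Hz) in a declared structure order. The concatenated
#' vector is a global fingerprint of one condition's brain state for one
#' animal/session.
#'
#' @param decompositions Named list (structure -> `fractal_decomposition` or
#'   residue vector on the common grid).
#' @param structure_list Structures to concatenate, in order; all must be
#'   present.
#' @param freq Frequency grid (required when plain vectors are given).
#' @param f_range Concatenated range, default `c(1, 300)` Hz.
#' @return Numeric vector of class `"state_vector"` with attributes
#'   `structures`, `freq_range`, `n_bins_per_structure`.
#' @export
build_state_vector <- function(decompositions, structure_list = NULL,
                               freq = NULL, f_range = c(1, 300)) {
  if (is.null(structure_list)) structure_list <- names(decompositions)
  missing <- setdiff(structure_list, names(decompositions))
  stop_if(length(missing) > 0L,
          "missing structure(s): ", paste(missing, collapse = ", "))
  parts <- lapply(structure_list, function(s) {
    d <- decompositions[[s]]
    if (inherits(d, "fractal_decomposition")) {
      sel <- d$freq >= f_range[1L] & d$freq <= f_range[2L]
      d$oscillatory_db[sel]
    } else {
      stop_if(is.null(freq), "`freq` required for plain residue vectors")
      sel <- freq >= f_range[1L] & freq <= f_range[2L]
      as.numeric(d)[sel]
    }
  })
  len <- vapply(parts, length, integer(1))
  stop_if(length(unique(len)) != 1L, "structures on different grids")
  structure(unlist(parts), class = "state_vector",
            structures = structure_list, freq_range = f_range,
            n_bins_per_structure = len[1L])
}

#' Correlate two brain-state vectors
#'
#' Pearson product-moment correlation; vectors must share length and
#' structure order.
#'
#' @param v1,v2 State vectors from [build_state_vector()] (plain numeric
#'   vectors of equal length are accepted).
#' @return Correlation coefficient in [-1, 1].
#' @export
correlate_states <- function(v1, v2) {
  stop_if(length(v1) != length(v2), "state vectors differ in length")
  s1 <- attr(v1, "structures")
  s2 <- attr(v2, "structures")
  stop_if(!is.null(s1) && !is.null(s2) && !identical(s1, s2),
          "structure orders differ")
  stop_if(stats::sd(v1) == 0 || stats::sd(v2) == 0,
          "zero-variance state vector; correlation undefined")
  stats::cor(as.numeric(v1), as.numeric(v2))
}

#' Treatment similarity against baseline and vehicle states
#'
#' Per animal, correlates the treatment state vector with that animal's
#' baseline and vehicle vectors; reports medians with 25th/75th percentiles
#' and, with at least `min_n` animals per group, Wilcoxon rank-sum tests
#' between treatments on the animal-level coefficients.
#'
#' @param treatment_vectors Named list: treatment -> named list (animal ->
#'   state vector).
#' @param baseline_vectors,vehicle_vectors Named lists (animal -> state
#'   vector).
#' @param min_n Minimum animals per group for testing (default 3).
#' @return List of class `"similarity_result"`: `coefficients` (data.frame
#'   treatment, animal, r_vs_baseline, r_vs_vehicle), `medians`, `tests`
#'   (possibly zero rows when suppressed).
#' @export
state_similarity_analysis <- function(treatment_vectors, baseline_vectors,
                                      vehicle_vectors, min_n = 3L) {
  rows <- list()
  for (tr in names(treatment_vectors)) {
    tv <- treatment_vectors[[tr]]
    for (an in names(tv)) {
      rb <- if (an %in% names(baseline_vectors))
        correlate_states(tv[[an]], baseline_vectors[[an]]) else NA_real_
      rv <- if (an %in% names(vehicle_vectors))
        correlate_states(tv[[an]], vehicle_vectors[[an]]) else NA_real_
      rows[[paste(tr, an)]] <- data.frame(
        treatment = tr, animal = an, r_vs_baseline = rb, r_vs_vehicle = rv,
        stringsAsFactors = FALSE)
    }
  }
  coefs <- do.call(rbind, rows)
  rownames(coefs) <- NULL
  med <- do.call(rbind, lapply(split(coefs, coefs$treatment), function(d) {
    qb <- stats::quantile(d$r_vs_baseline, c(0.25, 0.5, 0.75), na.rm = TRUE)
    qv <- stats::quantile(d$r_vs_vehicle, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(treatment = d$treatment[1L], n = nrow(d),
               r_baseline_q25 = qb[[1L]], r_baseline_med = qb[[2L]],
               r_baseline_q75 = qb[[3L]],
               r_vehicle_q25 = qv[[1L]], r_vehicle_med = qv[[2L]],
               r_vehicle_q75 = qv[[3L]], stringsAsFactors = FALSE)
  }))
  rownames(med) <- NULL
  tests <- list()
  trs <- names(treatment_vectors)
  if (length(trs) >= 2L) {
    cmb <- utils::combn(length(trs), 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- coefs[coefs$treatment == trs[cmb[1L, j]], ]
      b <- coefs[coefs$treatment == trs[cmb[2L, j]], ]
      for (ref in c("r_vs_baseline", "r_vs_vehicle")) {
        va <- a[[ref]][!is.na(a[[ref]])]
        vb <- b[[ref]][!is.na(b[[ref]])]
        if (length(va) < min_n || length(vb) < min_n) next
        if (stats::var(c(va, vb)) == 0) next  # degenerate: all identical
        rs <- rank_sum_test(va, vb)
        tests[[paste(trs[cmb[1L, j]], trs[cmb[2L, j]], ref)]] <- data.frame(
          treatment_a = trs[cmb[1L, j]], treatment_b = trs[cmb[2L, j]],
          reference = sub("r_vs_", "", ref), p = rs$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(treatment_a = character(0), treatment_b = character(0),
               reference = character(0), p = numeric(0))
  rownames(tests) <- NULL
  structure(list(coefficients = coefs, medians = med, tests = tests),
            class = "similarity_result")
}

#' Pairwise spectral similarity of one treatment against others
#'
#' Correlates the reference treatment's state vectors with each other
#' treatment's, per animal, and tests homogeneity of the coefficient
#' distributions across comparisons with a Kruskal-Wallis test (suppressed
#' for a single comparison group).
#'
#' @param reference_vectors Named list (animal -> state vector) for the
#'   reference treatment.
#' @param other_treatments Named list: treatment -> named list (animal ->
#'   state vector).
#' @return List: `coefficients` (comparison, animal, r), `test` (data.frame
#'   with H and p, or zero rows).
#' @export
pairwise_treatment_similarity <- function(reference_vectors,
                                          other_treatments) {
  rows <- list()
  for (tr in names(other_treatments)) {
    tv <- other_treatments[[tr]]
    for (an in intersect(names(tv), names(reference_vectors))) {
      rows[[paste(tr, an)]] <- data.frame(
        comparison = tr, animal = an,
        r = correlate_states(reference_vectors[[an]], tv[[an]]),
        stringsAsFactors = FALSE)
    }
  }
  stop_if(length(rows) == 0L, "no shared animals between treatments")
  coefs <- do.call(rbind, rows)
  rownames(coefs) <- NULL
  test <- data.frame(H = numeric(0), df = numeric(0), p = numeric(0))
  if (length(unique(coefs$comparison)) >= 2L &&
      stats::var(coefs$r) > 0) {
    kw <- kruskal_wallis(split(coefs$r, coefs$comparison))
    test <- data.frame(H = kw$statistic, df = kw$df, p = kw$p)
  }
  list(coefficients = coefs, test = test)
}
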