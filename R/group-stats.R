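#' Silver-Dunlap averaged correlation
#'
#' Averages Pearson correlations on the Fisher-Z scale: each r is
#' transformed by atanh, the transformed values are averaged and the mean
#' is back-transformed by tanh.  The spread is likewise computed on the
#' transformed scale and back-transformed.
#'
#' @param r Correlations, each strictly inside (-1, 1).
#' @return Tibble with `r_mean` (back-transformed mean), `r_sd`
#'   (back-transformed SD) and `n`.
#' @export
fisher_average <- function(r) {
  if (any(abs(r) >= 1)) abort("all correlations must satisfy |r| < 1")
  z <- atanh(r)
  tibble::tibble(
    r_mean = tanh(mean(z)),
    r_sd = if (length(z) > 1) tanh(sd(z)) else NA_real_,
    n = length(r)
  )
}

#' Default scalp adjacency for the 18-channel montage
#'
#' Neighbor pairs over the 10-20 montage used to define spatial contiguity
#' of Rueger areas: channels within one coronal row and between adjacent
#' rows are neighbors.  Symmetric and connected.  Override by passing your
#' own two-column edge table to [rueger_test()].
#'
#' @return Tibble with columns `from`, `to`.
#' @export
electrode_adjacency <- function() {
  edges <- rbind(
    c("Fp1", "Fp2"),
    c("F7", "F3"), c("F3", "Fz"), c("Fz", "F4"), c("F4", "F8"),
    c("T3", "C3"), c("C3", "Cz"), c("Cz", "C4"), c("C4", "T4"),
    c("T5", "P3"), c("P3", "P4"), c("P4", "T6"),
    c("O1", "O2"),
    c("Fp1", "F7"), c("Fp1", "F3"), c("Fp1", "Fz"),
    c("Fp2", "Fz"), c("Fp2", "F4"), c("Fp2", "F8"),
    c("F7", "T3"), c("F3", "C3"), c("Fz", "Cz"), c("F4", "C4"), c("F8", "T4"),
    c("T3", "T5"), c("C3", "P3"), c("Cz", "P3"), c("Cz", "P4"),
    c("C4", "P4"), c("T4", "T6"),
    c("T5", "O1"), c("P3", "O1"), c("P4", "O2"), c("T6", "O2")
  )
  tibble::tibble(from = edges[, 1], to = edges[, 2])
}

#' Rueger-area multiple-testing control
#'
#' Implements the Descriptive Data Analysis control over electrode sets:
#' channels with descriptively significant p-values (p < 0.05) are grouped
#' into spatially contiguous areas (connected components under the scalp
#' adjacency); an area of size k is globally significant when at least
#' ceil(k/3) of its p-values are <= 0.05/3 (0.017) AND at least ceil(k/2)
#' are <= 0.05/2 (0.025) -- the conjunction of the two Rueger criteria.
#'
#' @param pvals Named numeric vector of p-values, names = channel labels.
#' @param adjacency Edge tibble (`from`, `to`); default
#'   [electrode_adjacency()].
#' @param alpha Descriptive significance level (default 0.05).
#' @param operator `"and"` (default, the conjunction) or `"or"` for
#'   sensitivity analyses.
#' @return Tibble with one row per area: `area` (list-column of channels),
#'   `size`, `n_p017`, `n_p025`, `significant`.
#' @export
rueger_test <- function(pvals, adjacency = electrode_adjacency(),
                        alpha = 0.05, operator = c("and", "or")) {
  operator <- match.arg(operator)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  chans <- names(pvals)
  if (is.null(chans)) abort("pvals must be named by channel")
  nodes <- unique(c(adjacency$from, adjacency$to))
  missing <- setdiff(chans, nodes)
  if (length(missing)) {
    abort(paste0("channel(s) absent from adjacency: ",
                 paste(missing, collapse = ", ")))
  }
  sig <- chans[!is.na(pvals) & pvals < alpha]
  if (length(sig) == 0) {
    return(tibble::tibble(area = list(), size = integer(0),
                          n_p017 = integer(0), n_p025 = integer(0),
                          significant = logical(0)))
  }
  g <- igraph::graph_from_data_frame(adjacency, directed = FALSE,
                                     vertices = nodes)
  sub <- igraph::induced_subgraph(g, sig)
  comp <- igraph::components(sub)
  areas <- split(names(comp$membership), comp$membership)

  purrr::map_dfr(areas, function(a) {
    p <- pvals[a]
    k <- length(a)
    n017 <- sum(p <= alpha / 3)
    n025 <- sum(p <= alpha / 2)
    crit1 <- n017 >= ceiling(k / 3)
    crit2 <- n025 >= ceiling(k / 2)
    tibble::tibble(
      area = list(sort(a)), size = k,
      n_p017 = n017, n_p025 = n025,
      significant = if (operator == "and") crit1 && crit2 else crit1 || crit2
    )
  })
}

#' Normality-gated association test
#'
#' Chooses the test by Shapiro-Wilk normality (at 0.05) of the inputs:
#' for two numeric variables, Pearson correlation when both are Gaussian,
#' Spearman rank correlation otherwise; for a numeric variable against a
#' two-level group, independent-sample t-test when both groups are
#' Gaussian, Mann-Whitney U otherwise.  Group contrasts report eta-squared
#' (t^2/(t^2+df) for the t-test, z^2/(n-1) for Mann-Whitney).
#'
#' @param x Numeric variable.
#' @param y Second numeric variable (correlation mode), or `NULL`.
#' @param group Two-level factor/character (group-contrast mode), or `NULL`.
#' @return One-row tibble: `test`, `statistic`, `estimate` (r or group
#'   difference), `effect_size`, `p`, `n`, `normal`.
#' @export
gated_association <- function(x, y = NULL, group = NULL) {
  if (is.null(y) == is.null(group)) {
    abort("supply exactly one of `y` (correlation) or `group` (contrast)")
  }
  if (!is.null(y)) {
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 5) abort("at least 5 complete pairs are required")
    if (sd(x) == 0 || sd(y) == 0) abort("constant input; association undefined")
    normal <- shapiro_ok(x) && shapiro_ok(y)
    method <- if (normal) "pearson" else "spearman"
    ct <- suppressWarnings(cor.test(x, y, method = method))
    tibble::tibble(
      test = if (normal) "Pearson" else "Spearman",
      statistic = unname(ct$statistic),
      estimate = unname(ct$estimate),
      effect_size = unname(ct$estimate)^2,
      p = ct$p.value, n = length(x), normal = normal
    )
  } else {
    ok <- complete.cases(x, group)
    x <- x[ok]; group <- as.factor(as.character(group[ok]))
    if (nlevels(group) != 2) abort("`group` must have exactly 2 levels")
    xs <- split(x, group)
    if (any(lengths(xs) < 5)) abort("at least 5 observations per group")
    if (sd(x) == 0) abort("constant input; contrast undefined")
    normal <- all(vapply(xs, shapiro_ok, logical(1)))
    n <- length(x)
    if (normal) {
      tt <- t.test(xs[[1]], xs[[2]], var.equal = TRUE)
      es <- unname(tt$statistic)^2 /
        (unname(tt$statistic)^2 + unname(tt$parameter))
      tibble::tibble(
        test = "t", statistic = unname(tt$statistic),
        estimate = mean(xs[[1]]) - mean(xs[[2]]),
        effect_size = es, p = tt$p.value, n = n, normal = normal
      )
    } else {
      wt <- suppressWarnings(wilcox.test(xs[[1]], xs[[2]], exact = FALSE,
                                         correct = FALSE))
      u <- unname(wt$statistic)
      n1 <- length(xs[[1]]); n2 <- length(xs[[2]])
      z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n + 1) / 12)
      tibble::tibble(
        test = "Mann-Whitney", statistic = u,
        estimate = stats::median(xs[[1]]) - stats::median(xs[[2]]),
        effect_size = z^2 / (n - 1),
        p = wt$p.value, n = n, normal = normal
      )
    }
  }
}

shapiro_ok <- function(x) {
  n <- length(x)
  if (n < 3) return(FALSE)
  if (n > 5000) x <- x[seq(1, n, length.out = 5000)]
  shapiro.test(x)$p.value >= 0.05
}

#' Compare two independent correlations
#'
#' Fisher z-test: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`,
#' two-sided p.  Applied to rank correlations as an approximation.
#'
#' @param r1,r2 The two correlations (|r| < 1).
#' @param n1,n2 Their sample sizes (>= 4).
#' @return One-row tibble with `z` and `p_difference`.
#' @export
compare_independent_correlations <- function(r1, n1, r2, n2) {
  if (n1 < 4 || n2 < 4) abort("both samples must have n >= 4")
  if (abs(r1) >= 1 || abs(r2) >= 1) abort("correlations must satisfy |r| < 1")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z = z, p_difference = 2 * pnorm(-abs(z)))
}

#' Run the H1-H7 hypothesis battery
#'
#' Per channel, runs the designated normality-gated association between a
#' spectral parameter and a covariate, then applies [rueger_test()] over
#' the channel p-values:
#' \describe{
#'   \item{H1}{age vs spectral exponent alpha (flattening with age)}
#'   \item{H2}{age vs whitened maximal peak amplitude}
#'   \item{H3}{age vs maximal peak frequency}
#'   \item{H4}{sex vs slope-free intercept (default `lnC_2.5`), plus the
#'     companion sex vs peak-amplitude contrast expected to be null}
#'   \item{H5}{sex vs maximal peak frequency}
#'   \item{H6}{IQ vs peak amplitude, separately in women and men}
#'   \item{H7}{age vs alpha within IQ groups, correlations compared by
#'     [compare_independent_correlations()]}
#' }
#'
#' @param params Per-subject x per-channel parameter tibble (`subject_id`,
#'   `channel`, `alpha`, `lnC_2.5`, `f_maxPeak`, `lnPPeak`, ...).
#' @param covariates Per-subject tibble (`subject_id`, `age_years`, `sex`,
#'   optionally `iq_score`, `iq_group`).
#' @param hypotheses Subset of `c("H1", ..., "H7")` to run.
#' @param intercept_col Intercept column for H4 (default `"lnC_2.5"`).
#' @param adjacency Scalp adjacency for [rueger_test()].
#' @return A list of class `nrem_hypotheses`: `tests` (tibble: hypothesis,
#'   channel, test, estimate, p, ...), `areas` (tibble: hypothesis plus
#'   [rueger_test()] columns), and for H7 a `comparisons` tibble.
#' @export
run_hypotheses <- function(params, covariates,
                           hypotheses = paste0("H", 1:7),
                           intercept_col = "lnC_2.5",
                           adjacency = electrode_adjacency()) {
  need <- c("subject_id", "age_years", "sex")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) {
    abort(paste0("missing covariate column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(c("H6", "H7") %in% hypotheses)) {
    if (!"iq_score" %in% names(covariates) &&
        !"iq_group" %in% names(covariates)) {
      abort("missing covariate column(s): iq_score / iq_group")
    }
  }
  for (cl in c("age_years")) {
    if (all(is.na(covariates[[cl]]))) {
      abort(paste0("covariate column is empty: ", cl))
    }
  }
  df <- dplyr::inner_join(params,
                          dplyr::mutate(covariates,
                                        subject_id = as.character(.data$subject_id)),
                          by = "subject_id")
  by_ch <- split(df, df$channel)

  per_channel <- function(fun) {
    purrr::map_dfr(names(by_ch), function(ch) {
      res <- fun(by_ch[[ch]])
      if (is.null(res)) return(NULL)
      dplyr::bind_cols(tibble::tibble(channel = ch), res)
    })
  }

  tests <- list()
  areas <- list()
  comparisons <- NULL
  add <- function(h, tab) {
    if (is.null(tab) || nrow(tab) == 0) return(invisible(NULL))
    tests[[h]] <<- dplyr::bind_cols(tibble::tibble(hypothesis = h), tab)
    p <- stats::setNames(tab$p, tab$channel)
    ar <- rueger_test(p, adjacency)
    if (nrow(ar)) {
      areas[[h]] <<- dplyr::bind_cols(tibble::tibble(hypothesis = h), ar)
    }
  }

  if ("H1" %in% hypotheses) {
    add("H1", per_channel(function(d) gated_association(d$age_years, d$alpha)))
  }
  if ("H2" %in% hypotheses) {
    add("H2", per_channel(function(d) gated_association(d$age_years, d$lnPPeak)))
  }
  if ("H3" %in% hypotheses) {
    add("H3", per_channel(function(d) gated_association(d$age_years, d$f_maxPeak)))
  }
  if ("H4" %in% hypotheses) {
    add("H4", per_channel(function(d)
      gated_association(d[[intercept_col]], group = d$sex)))
    add("H4_peak_amplitude", per_channel(function(d)
      gated_association(d$lnPPeak, group = d$sex)))
  }
  if ("H5" %in% hypotheses) {
    add("H5", per_channel(function(d)
      gated_association(d$f_maxPeak, group = d$sex)))
  }
  if ("H6" %in% hypotheses) {
    for (sx in unique(df$sex)) {
      add(paste0("H6_", sx), per_channel(function(d) {
        d <- d[d$sex == sx, ]
        if (sum(complete.cases(d$iq_score, d$lnPPeak)) < 5) return(NULL)
        gated_association(d$iq_score, d$lnPPeak)
      }))
    }
  }
  if ("H7" %in% hypotheses) {
    grp <- if ("iq_group" %in% names(df)) {
      df$iq_group
    } else {
      ifelse(df$iq_score >= 120, "HIQ", "AIQ")
    }
    df$..iqg <- grp
    by_ch <- split(df, df$channel)
    for (g in c("AIQ", "HIQ")) {
      add(paste0("H7_", g), per_channel(function(d) {
        d <- d[d$..iqg == g, ]
        if (sum(complete.cases(d$age_years, d$alpha)) < 5) return(NULL)
        gated_association(d$age_years, d$alpha)
      }))
    }
    ta <- tests[["H7_AIQ"]]
    th <- tests[["H7_HIQ"]]
    if (!is.null(ta) && !is.null(th)) {
      common <- intersect(ta$channel, th$channel)
      comparisons <- purrr::map_dfr(common, function(ch) {
        a <- ta[ta$channel == ch, ]
        h <- th[th$channel == ch, ]
        dplyr::bind_cols(
          tibble::tibble(channel = ch, r_AIQ = a$estimate, n_AIQ = a$n,
                         r_HIQ = h$estimate, n_HIQ = h$n),
          compare_independent_correlations(a$estimate, a$n, h$estimate, h$n)
        )
      })
    }
  }

  structure(
    list(tests = dplyr::bind_rows(tests),
         areas = dplyr::bind_rows(areas),
         comparisons = comparisons),
    class = "nrem_hypotheses"
  )
}

#' @export
print.nrem_hypotheses <- function(x, ...) {
  hyps <- unique(x$tests$hypothesis)
  sig <- if (nrow(x$areas)) {
    unique(x$areas$hypothesis[x$areas$significant])
  } else {
    character(0)
  }
  cat(sprintf("<nrem_hypotheses> %d test block(s); significant areas: %s\n",
              length(hyps),
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  invisible(x)
}

#' @rdname run_hypotheses
#' @param x An `nrem_hypotheses` object.
#' @param ... Unused.
#' @method tidy nrem_hypotheses
#' @export
tidy.nrem_hypotheses <- function(x, ...) x$tests

#' @rdname run_hypotheses
#' @method glance nrem_hypotheses
#' @export
glance.nrem_hypotheses <- function(x, ...) {
  if (nrow(x$areas) == 0) {
    return(tibble::tibble(hypothesis = character(0), n_areas = integer(0),
                          any_significant = logical(0)))
  }
  dplyr::summarise(dplyr::group_by(x$areas, .data$hypothesis),
                   n_areas = dplyr::n(),
                   any_significant = any(.data$significant),
                   .groups = "drop")
}
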