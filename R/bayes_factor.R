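#' Evidence category for an oriented Bayes factor
#'
#' Bins an oriented (>= 1) Bayes factor on the conventional evidence scale:
#' (1, 3] not worth more than a bare mention, (3, 20] positive, (20, 150]
#' strong, above 150 very strong. Boundary values fall in the lower bin.
#'
#' @param bf Bayes factor, >= 1 (orient with [directional_bf()] first).
#' @return One of `"none"`, `"positive"`, `"strong"`, `"very_strong"`.
#' @export
bf_category <- function(bf) {
  if (any(is.na(bf)) || any(bf < 1))
    stop("bf must be >= 1; orient the hypothesis first")
  cut(bf, c(-Inf, 3, 20, 150, Inf),
      labels = c("none", "positive", "strong", "very_strong"),
      right = TRUE) |> as.character()
}

bf_stars <- function(category) {
  c(none = "", positive = "*", strong = "**",
    very_strong = "***")[category]
}

#' Directional Bayes factor for a difference in posterior draws
#'
#' Tests the composite hypotheses "A's component mean exceeds B's" against
#' its reverse. Under the shared, symmetric Normal(0, 20^2) prior the two
#' directional composites carry equal prior mass, so the Bayes factor
#' equals the posterior odds of the favored direction: paired differences
#' of equal-length draw streams (or the full cross-difference when the
#' lengths differ), ties split evenly, and BF = max(P(delta > 0),
#' P(delta < 0)) / min(...). When no draw falls on one side the BF is
#' unbounded; it is reported as `Inf` with display `"> 150"` when the
#' resolution bound (number of differences minus 1) exceeds 150.
#'
#' @param draws_a,draws_b Posterior draws of the component mean in the two
#'   strata.
#' @return List of class `hce_bf`: `bf`, `display`, `evidence`, `stars`,
#'   `sign` (+1 if A > B is favored), `p_positive`, `n_delta`, `method`.
#' @export
directional_bf <- function(draws_a, draws_b) {
  if (!length(draws_a) || !length(draws_b))
    stop("both draw sets must be nonempty")
  if (length(draws_a) == length(draws_b)) {
    delta <- draws_a - draws_b
    method <- "paired"
  } else {
    delta <- as.vector(outer(draws_a, draws_b, `-`))
    method <- "cross"
  }
  n <- length(delta)
  if (n < 1000)
    warning("fewer than 1000 difference draws; BF resolution limited to ",
            "about 1/", n)
  p_pos <- mean(delta > 0) + 0.5 * mean(delta == 0)
  p <- max(p_pos, 1 - p_pos)
  sign <- if (p_pos >= 0.5) 1L else -1L
  if (p == 1) {
    bf <- Inf
    display <- if (n - 1 > 150) "> 150" else paste0("> ", n - 1)
    evidence <- if (n - 1 > 150) "very_strong" else
      bf_category(max(n - 1, 1))
  } else {
    bf <- p / (1 - p)
    display <- if (bf > 150) "> 150" else formatC(bf, format = "fg",
                                                  digits = 3)
    evidence <- bf_category(bf)
  }
  structure(list(bf = bf, display = display, evidence = evidence,
                 stars = unname(bf_stars(evidence)), sign = sign,
                 p_positive = p_pos, n_delta = n, method = method),
            class = "hce_bf")
}

#' @export
print.hce_bf <- function(x, ...) {
  dir <- if (x$sign > 0) "A > B" else "B > A"
  cat(sprintf("Directional Bayes factor: %s %s (%s, favoring %s; %d draws, %s)\n",
              x$display, x$stars, x$evidence, dir, x$n_delta, x$method))
  invisible(x)
}

#' Grid of directional Bayes factors between two strata
#'
#' For every month before death and disease group present in both strata's
#' posteriors, the directional Bayes factor of the difference in component
#' means, oriented as `stratum_a - stratum_b`. Cells absent from either
#' stratum are marked absent.
#'
#' @param fit An [hce_fit()] with at least the two requested strata.
#' @param stratum_a,stratum_b Stratum labels as in `names(fit$n_g)`.
#' @param ttd Months before death to tabulate (default 0:12).
#' @return data.frame with columns `stratum_pair`, `ttd`, `disease`, `bf`,
#'   `display`, `stars`, `evidence`, `sign`.
#' @export
bf_table <- function(fit, stratum_a, stratum_b, ttd = 0:12) {
  stopifnot(stratum_a %in% names(fit$n_g), stratum_b %in% names(fit$n_g))
  pair <- paste(stratum_a, "-", stratum_b)
  rows <- list()
  for (t in ttd) {
    ca <- fit$cells[[paste0(stratum_a, ":", t)]]
    cb <- fit$cells[[paste0(stratum_b, ":", t)]]
    for (d in disease_groups()) {
      ja <- if (!is.null(ca)) match(d, ca$diseases) else NA
      jb <- if (!is.null(cb)) match(d, cb$diseases) else NA
      if (is.na(ja) || is.na(jb)) {
        rows[[length(rows) + 1L]] <-
          data.frame(stratum_pair = pair, ttd = t, disease = d,
                     bf = NA_real_, display = "absent", stars = "",
                     evidence = NA_character_, sign = NA_integer_)
        next
      }
      r <- directional_bf(ca$mu_draws[, ja], cb$mu_draws[, jb])
      rows[[length(rows) + 1L]] <-
        data.frame(stratum_pair = pair, ttd = t, disease = d,
                   bf = r$bf, display = r$display, stars = r$stars,
                   evidence = r$evidence, sign = r$sign)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
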