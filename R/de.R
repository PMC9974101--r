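# Gene-wise two-group linear model with empirical-Bayes variance moderation.
#
# Per gene g: beta_g = mean(group_a) - mean(group_b) on the log2 expression
# scale, with residual variance s2_g on d residual df. The gene-wise
# variances are shrunk toward a common prior: the hyperparameters (s0^2, d0)
# are estimated by the method of moments on log s2 (Smyth 2004), the
# posterior variance is s2~ = (d0 s0^2 + d s2) / (d0 + d), and the moderated
# t = beta / (s~ * sqrt(1/n_a + 1/n_b)) is referred to t on d0 + d df.

#' Specify a two-group contrast
#'
#' @param name Label for the contrast (e.g. `"T2Di_minus_vs_HC"`).
#' @param group_a,group_b Group labels; the log2 fold change is
#'   `mean(group_a) - mean(group_b)`, so `group_a` is the "numerator".
#' @param segment Optional segment restriction (absent in bulk mode).
#' @return A list of class `contrast_spec`.
#' @export
contrast_spec <- function(name, group_a, group_b, segment = NULL) {
  if (identical(group_a, group_b)) stop("group_a and group_b must differ", call. = FALSE)
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 segment = segment),
            class = "contrast_spec")
}

#' Gene-wise two-group ordinary least squares
#'
#' @param expr Numeric matrix (genes x units) of log2-scale expression.
#' @param metadata Tibble with `unit_id`, `group` and, if the spec restricts
#'   to a segment, `segment`.
#' @param spec A [contrast_spec()].
#' @return A `moderated_fit`: per-gene tibble (`gene`, `beta`, `s2`, `df`,
#'   `mean_a`, `mean_b`, `testable`) plus group sizes and the (not yet
#'   estimated) moderation hyperparameters. Genes with zero variance across
#'   all selected units are flagged untestable.
#' @export
fit_contrast <- function(expr, metadata, spec) {
  stopifnot(is.matrix(expr), inherits(spec, "contrast_spec"))
  md <- metadata
  if (!is.null(spec$segment)) {
    if (!"segment" %in% names(md)) stop("spec has a segment but metadata does not",
                                        call. = FALSE)
    md <- md[!is.na(md$segment) & md$segment == spec$segment, , drop = FALSE]
  }
  md <- md[md$unit_id %in% colnames(expr), , drop = FALSE]
  ua <- md$unit_id[as.character(md$group) == spec$group_a]
  ub <- md$unit_id[as.character(md$group) == spec$group_b]
  n_a <- length(ua); n_b <- length(ub)
  if (n_a < 2 || n_b < 2) {
    stop(sprintf("contrast '%s'%s: need >= 2 units per group (got %d vs %d)",
                 spec$name,
                 if (is.null(spec$segment)) "" else paste0(" [", spec$segment, "]"),
                 n_a, n_b), call. = FALSE)
  }
  xa <- expr[, ua, drop = FALSE]
  xb <- expr[, ub, drop = FALSE]
  mean_a <- rowMeans(xa)
  mean_b <- rowMeans(xb)
  rss <- rowSums((xa - mean_a)^2) + rowSums((xb - mean_b)^2)
  d <- n_a + n_b - 2
  s2 <- rss / d
  all_var <- apply(expr[, c(ua, ub), drop = FALSE], 1, var)
  testable <- all_var > 0
  fit <- tibble::tibble(
    gene = rownames(expr),
    beta = unname(mean_a - mean_b),
    s2 = unname(s2),
    df = d,
    mean_a = unname(mean_a),
    mean_b = unname(mean_b),
    testable = unname(testable)
  )
  structure(list(table = fit, n_a = n_a, n_b = n_b,
                 stdev_unscaled = sqrt(1 / n_a + 1 / n_b),
                 d0 = NA_real_, s02 = NA_real_, spec = spec,
                 moderated = FALSE),
            class = "moderated_fit")
}

#' Newton inversion of the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0`; used by the moment estimator of the
#' prior degrees of freedom.
#'
#' @param x Positive numeric vector.
#' @return `y` with `trigamma(y) = x` (Inf maps to 0-limit behaviour).
#' @keywords internal
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(NA_real_)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes variance moderation
#'
#' Estimates the prior variance `s0^2` and prior df `d0` by the method of
#' moments on `log(s2)` over testable genes, then fills posterior variances,
#' moderated t statistics and two-sided p values. `d0 = 0` reproduces the
#' ordinary t test; `d0 = Inf` pools all genes to the common prior variance.
#'
#' @param fit A `moderated_fit` from [fit_contrast()].
#' @param d0,s02 Optional hyperparameter overrides (both must be given
#'   together); otherwise estimated from the data.
#' @return The fit with `d0`, `s02` set and columns `s2_post`, `t`, `p_value`
#'   added to `fit$table`.
#' @export
ebayes_moderate <- function(fit, d0 = NULL, s02 = NULL) {
  stopifnot(inherits(fit, "moderated_fit"))
  tab <- fit$table
  if (!any(tab$testable)) stop("all genes are untestable", call. = FALSE)
  if (is.null(d0) != is.null(s02)) {
    stop("supply both d0 and s02, or neither", call. = FALSE)
  }
  if (is.null(d0)) {
    est <- .fit_f_dist(tab$s2[tab$testable & tab$s2 > 0],
                       tab$df[tab$testable & tab$s2 > 0][1])
    d0 <- est$d0
    s02 <- est$s02
  }
  d <- tab$df
  s2_post <- if (is.infinite(d0)) {
    rep(s02, nrow(tab))
  } else if (d0 == 0) {
    tab$s2
  } else {
    (d0 * s02 + d * tab$s2) / (d0 + d)
  }
  t_stat <- tab$beta / (sqrt(s2_post) * fit$stdev_unscaled)
  df_total <- d0 + d
  p <- 2 * pt(-abs(t_stat), df = df_total)
  t_stat[!tab$testable] <- NA_real_
  p[!tab$testable] <- NA_real_
  tab$s2_post <- s2_post
  tab$t <- t_stat
  tab$df_total <- df_total
  tab$p_value <- p
  fit$table <- tab
  fit$d0 <- d0
  fit$s02 <- s02
  fit$moderated <- TRUE
  fit
}

# Method-of-moments fit of a scaled F prior to the sample variances
# (moments of log s2; Smyth 2004). No solution of the moment equation
# (variance of log s2 no larger than expected under a point prior) => d0 = Inf.
.fit_f_dist <- function(s2, d) {
  if (length(s2) < 10) {
    warning("fewer than 10 testable genes; hyperparameter estimate unstable",
            call. = FALSE)
  }
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  e_mean <- mean(e)
  e_var <- var(e)
  excess <- e_var - trigamma(d / 2)
  if (is.na(excess) || excess <= 0) {
    return(list(d0 = Inf, s02 = exp(e_mean)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s02 <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around `p.adjust(method = "BH")`: sorted ascending,
#' `q_(i) = min_{j >= i} (m p_(j) / j)` clipped to 1, returned in the input
#' order. `NA`s (untestable genes) pass through and do not count toward `m`.
#'
#' @param p Numeric vector of p values in `[0, 1]` (NAs allowed).
#' @return Adjusted p values in the original order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Run two-group contrasts per segment
#'
#' For each contrast and each segment (all segments in the metadata when the
#' spec does not fix one; a single unsegmented stratum in bulk mode), fits
#' the gene-wise model, moderates, and applies BH within that
#' (contrast, segment) gene list.
#'
#' @param expr Log2-scale expression matrix (genes x units), typically
#'   pseudobulk [normalize_log_cpm()] output.
#' @param metadata Unit metadata (`unit_id`, `group`, optional `segment`).
#' @param specs A list of [contrast_spec()] objects.
#' @return A tibble of class `contrast_result`: `gene`, `segment`,
#'   `contrast`, `log2FC`, `t`, `p_value`, `fdr`, `mean_a`, `mean_b`,
#'   `testable`. Untestable genes carry `NA` statistics.
#' @export
run_contrasts <- function(expr, metadata, specs) {
  if (inherits(specs, "contrast_spec")) specs <- list(specs)
  segmented <- "segment" %in% names(metadata) && !all(is.na(metadata$segment))
  out <- purrr::map_dfr(specs, function(spec) {
    segs <- if (!is.null(spec$segment)) {
      spec$segment
    } else if (segmented) {
      unique(stats::na.omit(metadata$segment))
    } else {
      NA_character_
    }
    purrr::map_dfr(segs, function(seg) {
      sp <- spec
      sp$segment <- if (is.na(seg)) NULL else seg
      fit <- ebayes_moderate(fit_contrast(expr, metadata, sp))
      tab <- fit$table
      tibble::tibble(
        gene = tab$gene,
        segment = ifelse(is.na(seg), NA_character_, seg),
        contrast = spec$name,
        log2FC = tab$beta,
        t = tab$t,
        p_value = tab$p_value,
        fdr = bh_adjust(tab$p_value),
        mean_a = tab$mean_a,
        mean_b = tab$mean_b,
        testable = tab$testable
      )
    })
  })
  class(out) <- c("contrast_result", class(out))
  out
}

#' @method tidy moderated_fit
#' @export
tidy.moderated_fit <- function(x, ...) {
  tab <- x$table
  tab$contrast <- x$spec$name
  tab
}

#' @method glance moderated_fit
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble::tibble(
    contrast = x$spec$name,
    segment = if (is.null(x$spec$segment)) NA_character_ else x$spec$segment,
    n_genes = nrow(x$table),
    n_testable = sum(x$table$testable),
    n_a = x$n_a, n_b = x$n_b,
    d0 = x$d0, s02 = x$s02,
    moderated = x$moderated
  )
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("<moderated_fit> %s: %d genes, %d vs %d units%s\n",
              x$spec$name, nrow(x$table), x$n_a, x$n_b,
              if (x$moderated) sprintf(", d0 = %.3g, s0^2 = %.3g", x$d0, x$s02)
              else " (not yet moderated)"))
  invisible(x)
}
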