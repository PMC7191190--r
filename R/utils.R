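#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join semi_join bind_rows bind_cols distinct
#'   rename n across all_of slice_min first count pull relocate
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_lgl map_chr map2 pmap imap list_rbind
#' @importFrom stats median rbeta rexp rnorm runif rbinom p.adjust
#'   fisher.test chisq.test kruskal.test cor pchisq pnorm setNames quantile
#' @importFrom utils head modifyList packageVersion
NULL

# Coerce a beta container (matrix or data.frame with probe-id first column /
# rownames) to a numeric matrix, probes x samples.
as_beta_matrix <- function(beta, arg = "beta") {
  if (is.data.frame(beta)) {
    first <- beta[[1]]
    if (is.character(first) || is.factor(first)) {
      ids <- as.character(first)
      beta <- as.matrix(beta[, -1, drop = FALSE])
      rownames(beta) <- ids
    } else {
      beta <- as.matrix(beta)
    }
  }
  if (!is.matrix(beta) || !is.numeric(beta)) {
    abort(sprintf("`%s` must be a numeric matrix or a data frame of beta values.", arg))
  }
  if (is.null(rownames(beta))) {
    abort(sprintf("`%s` must have probe IDs as rownames (or first column).", arg))
  }
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(beta))
    abort(sprintf(
      "`%s` contains %d value(s) outside [0, 1]; first offender: probe '%s', sample '%s' (%.4g).",
      arg, length(bad), rownames(beta)[i[1]],
      colnames(beta)[i[2]] %||% as.character(i[2]), beta[bad[1]]
    ))
  }
  beta
}

check_fraction <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) abort(sprintf("`%s` must lie in %s.", name, if (open) "(0, 1)" else "[0, 1]"))
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}

# Beta draws parameterized by (mean, concentration); keeps values inside [0, 1]
# without clipping dominating the distribution.
rbeta_mc <- function(n, mean, concentration) {
  mean <- pmin(pmax(mean, 1e-4), 1 - 1e-4)
  rbeta(n, shape1 = mean * concentration, shape2 = (1 - mean) * concentration)
}
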