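#' Pearson correlation of trajectory time series
#'
#' Computes the pairwise Pearson product-moment correlation of metabolite
#' and/or enzyme-level time series on the trajectory's uniform reporting
#' grid.  Series with zero variance (constants) get the sentinel `NA`
#' ("undefined") rather than a propagating NaN.
#'
#' @param traj a `ccm_trajectory`.
#' @param variables names of metabolites and/or enzymes (default: every
#'   metabolite plus every forced enzyme).
#' @return A `ccm_cor` object: the correlation matrix with dimnames, plus
#'   the selected series as attribute `"series"`.
#' @export
correlate_trajectory <- function(traj, variables = NULL) {
  if (nrow(traj) < 2) abort_config("need at least two time points")
  mets <- attr(traj, "metabolites")
  E <- attr(traj, "enzymes")
  enzymes <- colnames(E)
  variables <- variables %||% c(mets, names(attr(traj, "program")))
  bad <- setdiff(variables, c(mets, enzymes))
  if (length(bad)) {
    abort_config(paste0("unknown variable(s): ", paste(bad, collapse = ", ")))
  }
  X <- vapply(variables, function(v) {
    if (v %in% mets) traj[[v]] else E[, v]
  }, numeric(nrow(traj)))
  sds <- apply(X, 2, stats::sd)
  R <- suppressWarnings(cor(X))
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  diag(R) <- ifelse(sds == 0, NA_real_, 1)
  structure(R, series = X, class = c("ccm_cor", class(R)))
}

#' @export
print.ccm_cor <- function(x, digits = 3, ...) {
  cat("<ccm_cor> Pearson correlations over", nrow(attr(x, "series")),
      "time points\n")
  print(round(unclass(x)[, , drop = FALSE], digits))
  invisible(x)
}

#' @export
tidy.ccm_cor <- function(x, ...) {
  R <- unclass(x)
  attr(R, "series") <- NULL
  df <- as.data.frame(as.table(R), stringsAsFactors = FALSE)
  names(df) <- c("variable_a", "variable_b", "r")
  tibble::as_tibble(df)
}

#' Write a labelled correlation-matrix CSV
#' @param x a `ccm_cor`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cor_csv <- function(x, path) {
  R <- unclass(x)
  attr(R, "series") <- NULL
  write.csv(as.data.frame(R), path, row.names = TRUE)
  invisible(path)
}

#' @export
autoplot.ccm_cor <- function(object, ...) {
  df <- tidy.ccm_cor(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable_a,
                                   y = .data$variable_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "white",
                                  high = "black", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
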