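#' Step test: steady-state PEP response to one enzyme's level
#'
#' Holds one enzyme at a constant multiple of its nominal level, relaxes the
#' network to its new steady state and reports the ratio of the new to the
#' nominal steady-state concentration of the target metabolite.
#'
#' @param net a [metabolic_network()].
#' @param enzyme reaction identifier.
#' @param factor constant enzyme level (1.5 = raised 50% above nominal).
#' @param target metabolite whose response is measured (default `"pep"`).
#' @return Dimensionless concentration ratio.
#' @export
step_test <- function(net, enzyme, factor = 1.5, target = "pep") {
  if (!enzyme %in% net$reactions) {
    abort_config(paste0("unknown reaction '", enzyme, "'"))
  }
  if (factor <= 0) abort_config("step factor must be positive")
  if (factor == 1) return(1)
  e <- setNames(factor, enzyme)
  ss <- find_steady_state(net, enzymes = e)
  ss[[target]] / net$steady_state[[target]]
}

#' Step-test sensitivity screen over all enzymes
#'
#' Runs [step_test()] for every reaction and flags the enzymes whose
#' steady-state response departs from 1 by more than `threshold` (two-sided:
#' both production-increasing and production-decreasing enzymes flag).
#' Non-converging step tests are reported with `NA` ratios instead of
#' aborting the screen.
#'
#' @param net a [metabolic_network()].
#' @param factor step multiple (default 1.5).
#' @param threshold flagging threshold on `|ratio - 1|` (default 0.02).
#' @param target response metabolite.
#' @return A `sensitivity_screen` tibble with columns `enzyme`, `ratio`,
#'   `flagged`, `converged`, plus attributes `flagged` (names ordered by
#'   effect size, ties alphabetical), `factor` and `threshold`.
#' @export
#' @examples
#' \donttest{
#' screen <- sensitivity_screen(ccm_network())
#' attr(screen, "flagged")
#' }
sensitivity_screen <- function(net, factor = 1.5, threshold = 0.02,
                               target = "pep") {
  ratios <- vapply(net$reactions, function(rx) {
    tryCatch(step_test(net, rx, factor, target),
             oscimet_numeric_error = function(e) NA_real_)
  }, numeric(1))
  flagged <- !is.na(ratios) & abs(ratios - 1) > threshold
  out <- tibble::tibble(enzyme = net$reactions, ratio = unname(ratios),
                        flagged = unname(flagged),
                        converged = !is.na(unname(ratios)))
  ord <- order(-abs(out$ratio - 1), out$enzyme)
  flagged_names <- out$enzyme[ord][out$flagged[ord]]
  structure(out,
            flagged = flagged_names, factor = factor, threshold = threshold,
            class = c("sensitivity_screen", class(out)))
}

#' @export
tidy.sensitivity_screen <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("enzyme", "ratio", "flagged", "converged")])
}

#' @export
glance.sensitivity_screen <- function(x, ...) {
  tibble::tibble(n_enzymes = nrow(x), n_flagged = sum(x$flagged),
                 factor = attr(x, "factor"), threshold = attr(x, "threshold"))
}

#' Write the screen as a Fig-2-style CSV (enzyme, ratio, flagged)
#' @param screen a `sensitivity_screen`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(screen, path) {
  write.csv(tidy.sensitivity_screen(screen), path, row.names = FALSE)
  invisible(path)
}

#' @export
autoplot.sensitivity_screen <- function(object, ...) {
  df <- tidy.sensitivity_screen(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$enzyme, y = .data$ratio,
                                   fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "grey70")) +
    ggplot2::labs(y = "steady-state PEP ratio", x = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
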