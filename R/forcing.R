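#' Time-varying enzyme-level profiles
#'
#' A profile describes one enzyme's dimensionless level over time.  Cosine
#' profiles follow `h + A cos(omega t + phi)` (or `h - A cos(...)` when
#' `inverted`, for anti-phase circuit members); square profiles replace the
#' cosine by its sign (50% duty cycle); constant profiles return `h`
#' unclamped (so knockouts at 0 and strong overexpression above the wave
#' ceiling are expressible).  Periodic waveforms are clamped to
#' `[e_min, e_max]`, the implementable expression range (default 1/20 to 20
#' times the nominal level); a rectified large-amplitude cosine is how the
#' waves reach the vicinity of both bounds.
#'
#' @param enzyme reaction identifier.
#' @param waveform `"cosine"`, `"square"` or `"constant"`.
#' @param A amplitude, dimensionless, >= 0.
#' @param omega angular frequency, rad/s, >= 0.
#' @param phi phase, radians (stored modulo 2 pi).
#' @param h bias level (the steady-state level is 1).
#' @param e_min,e_max clamp bounds for periodic waveforms.
#' @param inverted logical; negate the periodic deviation.
#' @return An `enzyme_profile` object.
#' @export
enzyme_profile <- function(enzyme, waveform = c("cosine", "square", "constant"),
                           A = 0, omega = 0, phi = 0, h = 1,
                           e_min = 1 / 20, e_max = 20, inverted = FALSE) {
  waveform <- match.arg(waveform)
  if (A < 0) abort_config("amplitude A must be >= 0")
  if (omega < 0) abort_config("frequency omega must be >= 0")
  if (e_min <= 0 || e_max < e_min) {
    abort_config("level bounds must satisfy e_max >= e_min > 0")
  }
  structure(list(enzyme = enzyme, waveform = waveform, A = A, omega = omega,
                 phi = phi %% (2 * pi), h = h, e_min = e_min, e_max = e_max,
                 inverted = isTRUE(inverted)),
            class = "enzyme_profile")
}

#' Evaluate an enzyme profile
#'
#' @param p an [enzyme_profile()].
#' @param t time(s), seconds (vectorized).
#' @return Enzyme level(s), dimensionless.
#' @export
eval_profile <- function(p, t) {
  if (p$waveform == "constant") {
    return(rep(p$h, length(t)))
  }
  osc <- cos(p$omega * t + p$phi)
  if (p$waveform == "square") osc <- sign(osc)
  raw <- if (p$inverted) p$h - p$A * osc else p$h + p$A * osc
  pmin(pmax(raw, p$e_min), p$e_max)
}

#' Enzyme-forcing programs
#'
#' A program is a named collection of [enzyme_profile()]s; enzymes without a
#' profile stay constant at their steady-state level 1.
#'
#' @param ... enzyme profiles (or a single list of them).
#' @return A `forcing_program` object.
#' @export
forcing_program <- function(...) {
  profs <- list(...)
  if (length(profs) == 1 && is.list(profs[[1]]) &&
      !inherits(profs[[1]], "enzyme_profile")) {
    profs <- profs[[1]]
  }
  ids <- vapply(profs, function(p) p$enzyme, character(1))
  if (anyDuplicated(ids)) {
    abort_config(paste0("duplicate profile for enzyme(s): ",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  structure(setNames(profs, ids), class = "forcing_program")
}

#' @export
print.forcing_program <- function(x, ...) {
  cat("<forcing_program> with", length(x), "forced enzyme(s)\n")
  for (p in x) {
    cat(sprintf("  %-9s %-8s A=%.4g omega=%.4g phi=%.4g h=%.4g [%g, %g]%s\n",
                p$enzyme, p$waveform, p$A, p$omega, p$phi, p$h, p$e_min,
                p$e_max, if (p$inverted) " inverted" else ""))
  }
  invisible(x)
}

validate_program <- function(net, program) {
  if (is.null(program)) return(forcing_program(list()))
  bad <- setdiff(names(program), net$reactions)
  if (length(bad)) {
    abort_config(paste0("program forces unknown reaction(s): ",
                        paste(bad, collapse = ", ")))
  }
  program
}

# constant program from a full enzyme-level vector (internal).
constant_program <- function(net, levels) {
  levels <- as_levels(net, levels)
  forced <- names(levels)[levels != 1]
  forcing_program(lapply(forced, function(id) {
    enzyme_profile(id, "constant", h = levels[[id]])
  }))
}

#' Enzyme-level function of a program
#'
#' @param net a [metabolic_network()].
#' @param program a [forcing_program()] (or `NULL` for the unforced network).
#' @return A function `f(t)` returning the full named enzyme-level vector.
#' @export
program_level_fn <- function(net, program = NULL) {
  program <- validate_program(net, program)
  base <- setNames(rep(1, length(net$reactions)), net$reactions)
  function(t) {
    e <- base
    for (p in program) e[[p$enzyme]] <- eval_profile(p, t)
    e
  }
}

# levels of every reaction on a time grid: |t| x n_reactions matrix.
program_level_matrix <- function(net, program, t) {
  program <- validate_program(net, program)
  E <- matrix(1, length(t), length(net$reactions),
              dimnames = list(NULL, net$reactions))
  for (p in program) E[, p$enzyme] <- eval_profile(p, t)
  E
}

#' Coupled light-circuit program
#'
#' Builds the anti-phase program of a single-input genetic switch: all member
#' enzymes share one frequency and phase; induced members (expressed under
#' the input) follow `1 + A cos`, repressed members the inverted wave
#' `1 - A cos`.  Induced members are assumed to be supplied from a plasmid on
#' top of the native copy, so their levels never drop below the nominal 1.0.
#'
#' @param omega shared angular frequency, rad/s.
#' @param phi shared phase, radians.
#' @param amplitudes named amplitude vector covering every member.
#' @param members list with character vectors `induced` and `repressed`.
#' @param e_max upper clamp (default 20).
#' @param waveform `"cosine"` or `"square"`.
#' @return A [forcing_program()].
#' @export
circuit_program <- function(omega, phi, amplitudes,
                            members = list(induced = c("GAPDH", "PFK"),
                                           repressed = "RPPK"),
                            e_max = 20, waveform = "cosine") {
  all_members <- c(members$induced, members$repressed)
  if (!length(all_members)) abort_config("circuit has no member enzymes")
  missing <- setdiff(all_members, names(amplitudes))
  if (length(missing)) {
    abort_config(paste0("no amplitude given for: ",
                        paste(missing, collapse = ", ")))
  }
  profs <- c(
    lapply(members$induced, function(id) {
      enzyme_profile(id, waveform, A = amplitudes[[id]], omega = omega,
                     phi = phi, e_min = 1, e_max = e_max)
    }),
    lapply(members$repressed, function(id) {
      enzyme_profile(id, waveform, A = amplitudes[[id]], omega = omega,
                     phi = phi, e_min = 1 / 20, e_max = e_max,
                     inverted = TRUE)
    }))
  forcing_program(profs)
}

# serialize a program to plain lists (scenario configs) and back.
program_to_list <- function(program) {
  lapply(unclass(program), function(p) {
    list(enzyme = p$enzyme, waveform = p$waveform, A = p$A, omega = p$omega,
         phi = p$phi, h = p$h, e_min = p$e_min, e_max = p$e_max,
         inverted = p$inverted)
  })
}

program_from_list <- function(x) {
  forcing_program(lapply(x, function(p) {
    enzyme_profile(p$enzyme, p$waveform %||% "cosine", A = p$A %||% 0,
                   omega = p$omega %||% 0, phi = p$phi %||% 0, h = p$h %||% 1,
                   e_min = p$e_min %||% (1 / 20), e_max = p$e_max %||% 20,
                   inverted = p$inverted %||% FALSE)
  }))
}
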