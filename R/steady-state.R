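## Tracee steady state of the whole-body model.

#' Tracee steady-state masses
#'
#' Solves the flux-balance system for the unlabeled (tracee) vitamin A masses
#' under constant dietary intake.  The absorbed intake
#' `absorption_efficiency * dietary_intake` passes through the absorption
#' delay into the chylomicron compartment and then plasma; each compartment's
#' inflow equals its outflow:
#' \deqn{m_4 = E I / L(5,4)}
#' \deqn{L(6,5) m_5 = (L(5,6) + L(0,6))\, m_6, \qquad L(7,5) m_5 = L(5,7) m_7}
#' with the plasma balance closing the system.  Total body stores are
#' `tbs = m_6 + m_7`.
#'
#' @param params A [rid_params] object.  `dietary_intake` may be zero, in
#'   which case all masses are zero.
#' @return An object of class `rid_masses`: list with `m_4`, `m_5`, `m_6`,
#'   `m_7` (µmol) and `tbs = m_6 + m_7`.
#' @export
#' @examples
#' steady_state(example_params())$tbs
steady_state <- function(params) {
  stopifnot(inherits(params, "rid_params"))
  p <- params
  if (p$l_5_4 <= 0 || p$l_5_7 <= 0 || (p$l_5_6 + p$l_0_6) <= 0)
    stop("degenerate parameters: steady state requires l_5_4 > 0, l_5_7 > 0 ",
         "and l_5_6 + l_0_6 > 0", call. = FALSE)
  absorbed <- p$absorption_efficiency * p$dietary_intake
  # plasma clearance net of recycling from the large store
  denom <- p$l_8_5 + p$l_6_5 * p$l_0_6 / (p$l_5_6 + p$l_0_6)
  if (denom <= 0)
    stop("degenerate parameters: no irreversible loss pathway ",
         "(l_8_5 and l_0_6 cannot both be zero)", call. = FALSE)
  m_4 <- absorbed / p$l_5_4
  m_5 <- absorbed / denom
  m_6 <- p$l_6_5 * m_5 / (p$l_5_6 + p$l_0_6)
  m_7 <- p$l_7_5 * m_5 / p$l_5_7
  structure(
    list(m_4 = m_4, m_5 = m_5, m_6 = m_6, m_7 = m_7, tbs = m_6 + m_7,
         params = p),
    class = "rid_masses"
  )
}

#' @export
print.rid_masses <- function(x, ...) {
  cat("Tracee steady-state masses (umol)\n")
  cat(sprintf("  chylomicron m4: %.4g   plasma m5: %.4g\n", x$m_4, x$m_5))
  cat(sprintf("  large store m6: %.4g   small store m7: %.4g\n", x$m_6, x$m_7))
  cat(sprintf("  total body stores: %.4g\n", x$tbs))
  invisible(x)
}
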