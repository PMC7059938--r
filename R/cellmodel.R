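#' Transjunctional voltage of an intercellular link (dual-clamp sampling)
#'
#' For the cellular strand discretized at `n_div` nodes per cell, the
#' junction between nodes `i` and `i + 1` is assigned the transjunctional
#' voltage `Vj = v[i + 1 + (n_div - 1)] - v[i - (n_div - 1)]`: the
#' potentials are sampled one cell away on each side of the junction,
#' mimicking how conductance-voltage relations are measured in dual
#' voltage-clamp experiments (electrodes in the two cell interiors).
#'
#' @param v nodal potentials, mV (1-based node vector).
#' @param link index `i` of the link's left node; the link must be
#'   intercellular, i.e. `i` is the last node of a cell (`i %% n_div == 0`)
#'   and not a strand end.
#' @param n_div subcellular divisions per cell.
#' @return Vj in mV.
#' @export
junction_vj <- function(v, link, n_div = 10) {
  n <- length(v)
  if (link %% n_div != 0 || link <= 0 || link >= n - 1)
    stop("link ", link, " is not an intercellular link for n_div = ", n_div,
         call. = FALSE)
  iL <- max(1L, link - (n_div - 1L))
  iR <- min(n, link + 1L + (n_div - 1L))
  v[iR] - v[iL]
}

#' Local conductivity of a link in the cellular strand
#'
#' Intracellular links carry the cytoplasmic conductivity; an intercellular
#' link carries `dx / (R_j * A_cell)` with the junction resistance
#' `R_j = 1/(beta * g_jo * g_j(Vj))` in the voltage-gated variant or
#' `R_j = 1/(beta * g_jo)` in the clamped variant. At `beta = 1` the
#' junction link conductance equals `g_jo` = 2.534 uS, about one whole-cell
#' cytoplasmic resistance.
#'
#' @param micro a [microstructure()] (its `regime` selects the variant:
#'   `"clamped"` ignores `vj`).
#' @param intercellular `TRUE` for a junction link.
#' @param vj transjunctional voltage, mV (voltage-gated links).
#' @param n_div subcellular divisions per cell (sets `dx = eps/n_div`).
#' @return link conductivity in mS/mm.
#' @export
local_conductivity <- function(micro, intercellular, vj = 0, n_div = 10) {
  stopifnot(inherits(micro, "microstructure"))
  if (!intercellular) return(micro$sigma_c)
  dx <- micro$eps / n_div
  g <- if (micro$regime == "clamped") 1 else micro_gj(vj, micro)
  dx * micro$beta * micro$g_jo * g / micro$A_cell
}
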