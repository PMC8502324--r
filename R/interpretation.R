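#' Garson percentage contributions
#'
#' Garson's absolute-weight decomposition of a trained single-hidden-
#' layer network: for input i and hidden node j the contribution is
#' `c_ij = |w_ij| * |v_j|`, normalized within each hidden node
#' (`r_ij = c_ij / sum_k c_kj`; nodes with all-zero inflow are skipped),
#' summed over nodes and rescaled so the percentages sum to 100.  Each
#' dummy column is scored separately.  Biases carry no input information
#' and are excluded.
#'
#' @param net a trained `mlp_net`.
#' @return named numeric vector of percentage contributions (sums to
#'   100).
#' @export
garson <- function(net) {
  stopifnot(inherits(net, "mlp_net"))
  C <- abs(net$W_in) * abs(net$w_out)   # hidden x inputs, row-scaled by |v_j|
  inflow <- rowSums(C)
  keep <- inflow > 0
  if (!any(keep)) stop_los("all weights are zero: importance undefined")
  R <- C[keep, , drop = FALSE] / inflow[keep]
  S <- colSums(R)
  pct <- 100 * S / sum(S)
  names(pct) <- colnames(net$W_in)
  pct
}

#' Direction of each input's contribution
#'
#' Sign of the summed synaptic connection-weight products
#' `sum_j w_ij * v_j` (the Olden-style overall connection weight): a
#' positive value means the input raises the predicted probability of
#' the outcome, a negative value lowers it.
#'
#' @param net a trained `mlp_net`.
#' @return character vector (`"positive"`, `"negative"` or `"zero"`),
#'   named by input column.
#' @export
contribution_signs <- function(net) {
  stopifnot(inherits(net, "mlp_net"))
  cw <- as.numeric(t(net$W_in) %*% net$w_out)
  out <- ifelse(cw > 0, "positive", ifelse(cw < 0, "negative", "zero"))
  names(out) <- colnames(net$W_in)
  out
}

#' Variable-importance report
#'
#' @param net a trained `mlp_net`.
#' @return data.frame with one row per input column: `column`,
#'   `garson_pct`, `sign`, sorted by decreasing contribution.
#' @export
importance_report <- function(net) {
  pct <- garson(net)
  sgn <- contribution_signs(net)
  out <- data.frame(column = names(pct), garson_pct = unname(pct),
                    sign = unname(sgn), stringsAsFactors = FALSE)
  out[order(-out$garson_pct), , drop = FALSE]
}
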