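#' The two-high-threshold source-monitoring model (2HTSM) as EQN text
#'
#' Reconstructs the 2HTSM for a design with items from an expected source
#' (tree `E`), an unexpected source (tree `U`), and new items (tree `N`).
#' Responses are "Source A", "Source B", or "New", giving nine categories
#' labelled `E_A, E_B, E_N, U_A, U_B, U_N, N_A, N_B, N_N` (tree, then
#' response).  These tree and category labels are this package's convention
#' for the standard model.
#'
#' Parameters: `D1`, `D2` = detection of old items from the expected and
#' unexpected source; `D3` = detection that an item is new; `d1`, `d2` =
#' source memory for the two sources; `a` = guessing "Source A" after
#' detection without source memory; `g` = guessing "Source A" when the item
#' was not detected; `b` = guessing "old" for undetected items.  The full
#' model has 8 parameters but only 6 free categories and is therefore not
#' identifiable without restrictions; the standard restrictions are
#' `D1 = D2 = D3`, `d1 = d2`, `a = g`.
#'
#' @return Character vector of EQN lines (first line is a comment).
#' @examples
#' model <- parse_eqn(eqn_2htsm())
#' restricted <- apply_restrictions(model, restrictions_2htsm())
#' @export
eqn_2htsm <- function() {
  c("# 2HTSM: source monitoring with expected (E), unexpected (U), new (N) items",
    "E E_A D1*d1",
    "E E_A D1*(1-d1)*a",
    "E E_A (1-D1)*b*g",
    "E E_B D1*(1-d1)*(1-a)",
    "E E_B (1-D1)*b*(1-g)",
    "E E_N (1-D1)*(1-b)",
    "U U_A D2*(1-d2)*a",
    "U U_A (1-D2)*b*g",
    "U U_B D2*d2",
    "U U_B D2*(1-d2)*(1-a)",
    "U U_B (1-D2)*b*(1-g)",
    "U U_N (1-D2)*(1-b)",
    "N N_A (1-D3)*b*g",
    "N N_B (1-D3)*b*(1-g)",
    "N N_N D3",
    "N N_N (1-D3)*(1-b)")
}

#' Standard identifying restrictions for the 2HTSM
#'
#' @return An `mpt_restrictions` object encoding `D1 = D2 = D3`, `d1 = d2`,
#'   `a = g`.
#' @export
restrictions_2htsm <- function() {
  parse_restrictions(c("D1 = D2 = D3", "d1 = d2", "a = g"))
}
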