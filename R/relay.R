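#' Score a two-step relay path
#'
#' @param flow1,flow2 Positive flows of the incoming and outgoing step.
#' @param mode `"mean"` (arithmetic mean, default), `"min"`, or
#'   `"geometric"`.
#' @return Numeric score (vectorized over flows).
#' @export
score_relay <- function(flow1, flow2, mode = c("mean", "min", "geometric")) {
  mode <- match.arg(mode)
  stopifnot(all(flow1 > 0), all(flow2 > 0))
  switch(mode,
         mean = (flow1 + flow2) / 2,
         min = pmin(flow1, flow2),
         geometric = sqrt(flow1 * flow2))
}

#' Enumerate two-step relay paths
#'
#' A relay path chains an incoming signal (cell i emits ligand L1 bound by
#' receptor R1 on cell j) with an outgoing signal from the same intermediate
#' cell j (ligand L2 bound by R2 on cell k). Both steps must carry at least
#' `min_flow`; i = k is allowed (back-signaling loops), i = j and j = k are
#' not. By default any received signal may precede any emitted signal from
#' the intermediate cell; an optional `link_table` (named list mapping a
#' receptor to the ligands it can license downstream) restricts step 2's
#' ligand given step 1's receptor.
#'
#' @param table Ligand-flow table (`source,target,ligand,receptor,flow`), as
#'   produced by [split_flows()].
#' @param min_flow Nonnegative flow threshold applied to both steps.
#' @param link_table Optional named list: `link_table[[receptor]]` is a
#'   character vector of permitted downstream ligands.
#' @param mode Scoring mode passed to [score_relay()].
#' @return Data frame with columns `source,ligand1,receptor1,via,ligand2,
#'   receptor2,target,flow1,flow2,score`, ordered by (source, ligand1,
#'   receptor1, via, ligand2, receptor2, target).
#' @export
enumerate_relays <- function(table, min_flow = 0, link_table = NULL,
                             mode = c("mean", "min", "geometric")) {
  mode <- match.arg(mode)
  stopifnot(min_flow >= 0,
            all(c("source", "target", "ligand", "receptor", "flow") %in%
                  names(table)))
  empty <- data.frame(source = character(), ligand1 = character(),
                      receptor1 = character(), via = character(),
                      ligand2 = character(), receptor2 = character(),
                      target = character(), flow1 = numeric(),
                      flow2 = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  t1 <- table[table$flow >= min_flow & table$flow > 0 &
                table$source != table$target, , drop = FALSE]
  if (nrow(t1) < 2) return(empty)
  step1 <- t1
  names(step1) <- c("source", "via", "ligand1", "receptor1", "flow1")
  step2 <- t1
  names(step2) <- c("via", "target", "ligand2", "receptor2", "flow2")
  out <- merge(step1, step2, by = "via")
  if (!is.null(link_table)) {
    allowed <- mapply(function(r1, l2) {
      lig <- link_table[[r1]]
      !is.null(lig) && l2 %in% lig
    }, out$receptor1, out$ligand2)
    out <- out[as.logical(allowed), , drop = FALSE]
  }
  if (nrow(out) == 0) return(empty)
  out$score <- score_relay(out$flow1, out$flow2, mode)
  out <- out[, c("source", "ligand1", "receptor1", "via", "ligand2",
                 "receptor2", "target", "flow1", "flow2", "score")]
  out <- out[order(out$source, out$ligand1, out$receptor1, out$via,
                   out$ligand2, out$receptor2, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
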