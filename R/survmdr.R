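#' Label genotype cells by cell-vs-rest log-rank sign
#'
#' The survival-MDR labeling rule: a populated cell is `HIGH` when the
#' log-rank O - E numerator of its subjects against all remaining
#' subjects is >= 0, `LOW` otherwise, `EMPTY` when unpopulated.  By the
#' residual/log-rank identity this coincides with [labelCells()] applied
#' to martingale residuals from the covariate-free null fit, but it is
#' computed here directly from the risk sets, so the two routes
#' cross-check each other.
#'
#' @param cells 0-based cell indices from [assignCells()].
#' @param time,status survival outcome.
#' @return character vector of length `3^k`, as for [labelCells()].
#' @export
survmdrLabelCells <- function(cells, time, status) {
  k <- attr(cells, "k")
  if (is.null(k)) k <- max(1L, ceiling(log(max(cells, na.rm = TRUE) + 1, 3)))
  nc <- 3L^k
  lab <- rep("EMPTY", nc)
  names(lab) <- as.character(seq_len(nc) - 1L)
  ok <- !is.na(cells)
  for (cell in unique(cells[ok])) {
    inCell <- ok & cells == cell
    if (all(inCell == ok)) {
      # every usable subject is in this cell: O - E is identically 0
      lab[as.character(cell)] <- "HIGH"
      next
    }
    lr <- logrankTest(time[ok], status[ok],
                      ifelse(inCell[ok], "cell", "rest"))
    oe <- sum(lr@observed - lr@expected)   # group 1 = "cell"
    lab[as.character(cell)] <- if (oe >= 0) "HIGH" else "LOW"
  }
  lab
}
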