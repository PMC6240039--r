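#' Published Sa Serra land-cover transition matrix (percent of area)
#'
#' The 1998-to-2016 land-cover transition matrix of the Sa Serra cork oak
#' landscape (Sardinia, Italy) as published for the study region, in percent
#' of total area; rows are 1998 classes, columns 2016 classes. Shipped as a
#' plain-text fixture and used to exercise the net-change accounting: cork
#' oak gains (5 + 4 + 1) minus losses (10 + 8) give a net change of -8
#' percentage points.
#'
#' @return Square numeric matrix with class names on both dimensions.
#' @examples
#' m <- saserra_transition()
#' net_change(m)
#' @export
saserra_transition <- function() {
  path <- system.file("extdata", "saserra_transition_1998_2016.csv",
                      package = "dixonscan", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$from
  m
}
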