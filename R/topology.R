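#' Build the three-level membrane topology
#'
#' The optimizer's fixed communication structure: one level-1 output membrane
#' (`m0`) with three level-2 children (`m01`, `m02`, `m03`), each of which has
#' three level-3 children (`m011` ... `m033`) — 13 membranes in total.
#' Bidirectional channels connect every parent-child pair and every pair of
#' siblings sharing a parent; the channel set is stored symmetrically (both
#' orderings present).
#'
#' Only the level-3 membranes hold particles; level-2 membranes aggregate the
#' local optima communicated upward, and the output membrane records the
#' global best.
#'
#' @return An object of class `tissue_topology`: list with `membrane_ids`,
#'   `level` (named integer vector), `children` (named list) and `channels`
#'   (two-column character matrix, symmetric).
#' @examples
#' topo <- build_topology()
#' length(topo$membrane_ids)  # 13
#' @export
build_topology <- function() {
  root <- "m0"
  level2 <- paste0("m0", 1:3)
  children <- list()
  children[[root]] <- level2
  level3 <- character(0)
  for (u in level2) {
    kids <- paste0(u, 1:3)
    children[[u]] <- kids
    level3 <- c(level3, kids)
  }
  ids <- c(root, level2, level3)
  level <- setNames(c(1L, rep(2L, 3), rep(3L, 9)), ids)

  pairs <- list()
  add <- function(a, b) pairs[[length(pairs) + 1L]] <<- c(a, b)
  for (parent in names(children)) {
    kids <- children[[parent]]
    for (k in kids) { add(parent, k); add(k, parent) }
    for (i in seq_along(kids))
      for (j in seq_along(kids))
        if (i != j) add(kids[i], kids[j])
  }
  channels <- do.call(rbind, pairs)
  colnames(channels) <- c("from", "to")
  structure(list(membrane_ids = ids, level = level,
                 children = children, channels = channels),
            class = "tissue_topology")
}

#' @export
print.tissue_topology <- function(x, ...) {
  cat(sprintf("<tissue_topology: %d membranes, levels 1/2/3 = %d/%d/%d, %d channel arcs>\n",
              length(x$membrane_ids), sum(x$level == 1L), sum(x$level == 2L),
              sum(x$level == 3L), nrow(x$channels)))
  invisible(x)
}
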