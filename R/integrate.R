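#' Intersect the two DE arms into beacon gene lists
#'
#' Genes called in the same direction by both the associative and the
#' random-variance arm become "beacon" genes. A gene significant in both
#' arms but with opposite directions is excluded from the beacons and
#' reported in \code{conflicts}. The overlap report gives, per
#' direction, the two list sizes, the intersection size, and whether one
#' list is a subset of the other.
#'
#' @param assoc,rvm DE result data.frames (as from [associativeDE()] and
#'   [classComparison()]) over the same gene universe, or lists with
#'   elements \code{up} and \code{down} of gene ids.
#' @return A \linkS4class{BeaconLists}.
#' @examples
#' a <- list(up = c("a", "b"), down = character(0))
#' r <- list(up = c("b", "c"), down = character(0))
#' beaconGenes(integrateLists(a, r), "up")
#' @export
integrateLists <- function(assoc, rvm) {
  pick <- function(x, dir) {
    if (is.data.frame(x))
      sort(x$gene[x$passed_filters & x$direction == dir])
    else sort(as.character(x[[dir]]))
  }
  up_a <- pick(assoc, "up"); down_a <- pick(assoc, "down")
  up_r <- pick(rvm, "up"); down_r <- pick(rvm, "down")
  conflicts <- sort(union(intersect(up_a, down_r),
                          intersect(down_a, up_r)))
  up_b <- setdiff(intersect(up_a, up_r), conflicts)
  down_b <- setdiff(intersect(down_a, down_r), conflicts)
  rep_row <- function(dir, A, B, AB)
    data.frame(direction = dir, n_assoc = length(A), n_rvm = length(B),
               n_beacon = length(AB),
               assoc_subset_of_rvm = length(setdiff(A, B)) == 0L,
               rvm_subset_of_assoc = length(setdiff(B, A)) == 0L)
  report <- rbind(rep_row("up", up_a, up_r, up_b),
                  rep_row("down", down_a, down_r, down_b))
  methods::new("BeaconLists", upAssoc = up_a, downAssoc = down_a,
               upRvm = up_r, downRvm = down_r,
               upBeacon = up_b, downBeacon = down_b,
               report = report, conflicts = conflicts)
}
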