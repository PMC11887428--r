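## Stereo descriptor perception.
##
## Priorities are CIP-like, not full CIP: atoms are ranked by atomic
## number, then iteratively refined by the sorted ranks of their
## neighbours (Morgan-style).  A tetravalent atom whose four substituents
## all receive distinct ranks is a stereocenter; its label is the parity
## ("R"/"S"-like) of the signed volume of the three highest-priority
## substituent vectors seen from the lowest.  The priority-ordered
## neighbour indices are stored with each center so that later assertions
## evaluate the same signed volume on new geometry -- labels are carried,
## never re-derived from fresh priorities, after geometry changes.

canonical_ranks <- function(m) {
  adj <- adjacency(m)
  n <- n_atoms(m)
  r <- element_row(m$atoms$element)$number * 100 + m$atoms$formal_charge
  r <- match(r, sort(unique(r)))
  repeat {
    key <- vapply(seq_len(n), function(i) {
      paste(r[i], paste(sort(r[adj[[i]]], decreasing = TRUE), collapse = ","))
    }, "")
    r2 <- match(key, sort(unique(key)))
    if (length(unique(r2)) == length(unique(r))) return(r2)
    r <- r2
  }
}

## rank substituent branches of atom i by BFS over canonical ranks;
## returns a priority order of the neighbour indices (highest first),
## or NULL if two branches tie.
branch_priorities <- function(m, i, adj, ranks) {
  nb <- adj[[i]]
  keys <- vapply(nb, function(j) {
    seen <- c(i, j)
    shell <- j
    parts <- sprintf("%04d", ranks[j])
    for (d in 1:6) {
      nxt <- setdiff(unique(unlist(adj[shell])), seen)
      if (length(nxt) == 0) break
      parts <- c(parts, paste(sprintf("%04d", sort(ranks[nxt], decreasing = TRUE)),
                              collapse = ""))
      seen <- c(seen, nxt)
      shell <- nxt
    }
    paste(parts, collapse = "|")
  }, "")
  if (anyDuplicated(keys)) return(NULL)
  nb[order(keys, decreasing = TRUE)]
}

parity_sign <- function(X, pr) {
  v1 <- X[pr[1], ] - X[pr[4], ]
  v2 <- X[pr[2], ] - X[pr[4], ]
  v3 <- X[pr[3], ] - X[pr[4], ]
  det(rbind(v1, v2, v3))
}

#' Perceive stereo descriptors
#'
#' Detects tetrahedral stereocenters and stereogenic double bonds and
#' assigns parity labels from the current geometry.  Priorities are
#' CIP-like (atomic number, then iterative neighbourhood refinement), not
#' strict CIP; labels are internally consistent and are what the
#' stereo-preservation assertions compare.
#'
#' @param m a `glyccs_molecule`.
#' @return A list with data frames `centers` (`atom`, `label`, and the
#'   priority-ordered neighbour columns `n1`..`n4`) and `double_bonds`
#'   (`a1`, `a2`, `hi`, `hj`, `label`).
#' @export
perceive_stereo <- function(m) {
  adj <- adjacency(m)
  n <- n_atoms(m)
  centers <- data.frame(atom = integer(), label = character(),
                        n1 = integer(), n2 = integer(),
                        n3 = integer(), n4 = integer())
  dbl <- data.frame(a1 = integer(), a2 = integer(),
                    hi = integer(), hj = integer(), label = character())
  if (n == 0 || nrow(m$bonds) == 0) return(list(centers = centers, double_bonds = dbl))
  ranks <- canonical_ranks(m)
  X <- coords(m)
  for (i in seq_len(n)) {
    if (length(adj[[i]]) != 4) next
    pr <- branch_priorities(m, i, adj, ranks)
    if (is.null(pr)) next
    s <- parity_sign(X, pr)
    centers <- rbind(centers,
                     data.frame(atom = i, label = if (s > 0) "R" else "S",
                                n1 = pr[1], n2 = pr[2], n3 = pr[3], n4 = pr[4]))
  }
  for (b in which(m$bonds$order == 2)) {
    i <- m$bonds$a1[b]; j <- m$bonds$a2[b]
    ni <- setdiff(adj[[i]], j); nj <- setdiff(adj[[j]], i)
    if (length(ni) < 1 || length(nj) < 1) next
    if (length(ni) == 2 && ranks[ni[1]] == ranks[ni[2]]) next
    if (length(nj) == 2 && ranks[nj[1]] == ranks[nj[2]]) next
    hi <- ni[which.max(ranks[ni])]; hj <- nj[which.max(ranks[nj])]
    ph <- dihedral_angle(X[hi, ], X[i, ], X[j, ], X[hj, ])
    lab <- if (abs(ph) < pi / 2) "Z" else "E"
    dbl <- rbind(dbl, data.frame(a1 = i, a2 = j, hi = hi, hj = hj, label = lab))
  }
  list(centers = centers, double_bonds = dbl)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Assert stereo preservation
#'
#' Re-evaluates the signed volume at every recorded stereocenter, using
#' the neighbour priority order frozen when the descriptors were
#' perceived, and errors if any parity flipped.  `index_map` translates
#' reference atom indices to indices in `m` (identity by default), which
#' lets the assertion run across charge models where one hydrogen was
#' added or removed.
#'
#' @param m a `glyccs_molecule` holding the current geometry.
#' @param reference stereo list to compare against (default `m$stereo`).
#' @param index_map integer vector mapping reference atom index ->
#'   index in `m`, or `NULL` for identity.
#' @return `TRUE` invisibly; otherwise an error naming the first inverted
#'   center.
#' @export
assert_stereo <- function(m, reference = m$stereo, index_map = NULL) {
  if (is.null(reference) || nrow(reference$centers) == 0) return(invisible(TRUE))
  X <- coords(m)
  map <- function(i) if (is.null(index_map)) i else index_map[i]
  for (r in seq_len(nrow(reference$centers))) {
    ctr <- reference$centers[r, ]
    pr <- map(c(ctr$n1, ctr$n2, ctr$n3, ctr$n4))
    if (anyNA(pr)) next  # a mapped neighbour no longer exists (moved proton)
    s <- parity_sign(X, pr)
    lab <- if (s > 0) "R" else "S"
    if (lab != ctr$label)
      stop(sprintf("stereocenter at atom %d inverted (%s -> %s)",
                   ctr$atom, ctr$label, lab), call. = FALSE)
  }
  invisible(TRUE)
}
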