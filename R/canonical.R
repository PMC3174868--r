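# Canonical keys for constitutions.
#
# The key is a serialization of the graph after relabeling by a canonical
# permutation (BLISS, via igraph). Bond orders are carried as vertex colors on
# subdivision vertices: each bond becomes an auxiliary vertex colored by its
# (Kekule-normalized) order, joined to its two endpoints. Vertex-colored
# canonical labeling of that graph is then exactly labeled-graph isomorphism on
# (element, charge, H count, bond order).

atom_color <- function(element, charge, n_h) {
  idx <- match(element, .ELEMENTS)
  1000L + idx * 100L + (charge + 8L) * 10L + n_h
}

#' Canonical key of a constitution
#'
#' Returns a string that is identical for any two constitutions whose labeled
#' graphs (element, formal charge, implicit H count, bond order) are
#' isomorphic, and different otherwise. Six-membered C/N rings with
#' alternating single/double bonds are normalized to an aromatic bond token
#' first, so the two Kekule forms of such a ring share one key. Atom `id`
#' labels are ignored: the key identifies the constitution, not the NMR shift
#' assignment.
#'
#' @param m A `constitution`.
#' @return A single string.
#' @examples
#' a <- constitution(data.frame(element = c("C", "C", "O"), n_h = c(3, 2, 1)),
#'                   data.frame(i = 1:2, j = 2:3, order = 1))
#' b <- constitution(data.frame(element = c("O", "C", "C"), n_h = c(1, 2, 3)),
#'                   data.frame(i = 1:2, j = 2:3, order = 1))
#' identical(canonical_key(a), canonical_key(b)) # TRUE
#' @export
canonical_key <- function(m) {
  n <- n_atoms(m)
  nb <- nrow(m$bonds)
  orders <- normalized_bond_orders(m)
  colors <- c(atom_color(m$atoms$element, m$atoms$charge, m$atoms$n_h), orders)
  if (nb == 0L) {
    a <- m$atoms
    return(paste0(a$element, charge_token(a$charge), "H", a$n_h, "|"))
  }
  edges <- integer(0)
  for (k in seq_len(nb)) {
    bv <- n + k
    edges <- c(edges, m$bonds$i[k], bv, bv, m$bonds$j[k])
  }
  g <- igraph::make_graph(edges, n = n + nb, directed = FALSE)
  perm <- igraph::canonical_permutation(g, colors = as.integer(colors))$labeling
  # position of atom v in the canonical order
  atom_rank <- rank(perm[seq_len(n)])
  ord <- order(atom_rank)
  a <- m$atoms[ord, ]
  atom_str <- paste0(a$element, charge_token(a$charge), "H", a$n_h,
                     collapse = ",")
  bi <- atom_rank[m$bonds$i]
  bj <- atom_rank[m$bonds$j]
  lo <- pmin(bi, bj); hi <- pmax(bi, bj)
  ek <- order(lo, hi)
  bond_str <- paste0(lo[ek], "-", hi[ek], ":", order_token(orders[ek]),
                     collapse = ",")
  paste0(atom_str, "|", bond_str)
}

charge_token <- function(charge) {
  ifelse(charge == 0L, "", sprintf("%+d", charge))
}

order_token <- function(ord) {
  c("1", "2", "3", "a")[ord]
}
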