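#' Construct a molecular constitution
#'
#' A constitution is a connected molecular graph without stereochemistry: heavy
#' atoms with formal charges and implicit hydrogen counts, plus bonds with
#' integer orders. It is the unit of output of computer-assisted structure
#' elucidation.
#'
#' @param atoms A data frame with columns `element` (symbol), `charge`
#'   (integer, default 0) and `n_h` (implicit hydrogens); an optional `id`
#'   column carries the NMR atom labels used in correlation data.
#' @param bonds A data frame with columns `i`, `j` (1-based atom indices,
#'   any order) and `order` (1, 2 or 3). May have zero rows for a single
#'   heavy atom.
#' @param validate Check valence conservation and connectivity (default TRUE).
#' @return An object of class `constitution`.
#' @examples
#' ethanol <- constitution(
#'   atoms = data.frame(element = c("C", "C", "O"), n_h = c(3, 2, 1)),
#'   bonds = data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 1))
#' )
#' @export
constitution <- function(atoms, bonds, validate = TRUE) {
  atoms <- as_tibble(atoms)
  if (!"charge" %in% names(atoms)) atoms$charge <- 0L
  if (!"id" %in% names(atoms)) atoms$id <- NA_character_
  atoms <- tibble(
    id = as.character(atoms$id),
    element = as.character(atoms$element),
    charge = as.integer(atoms$charge),
    n_h = as.integer(atoms$n_h)
  )
  bonds <- as_tibble(bonds)
  if (nrow(bonds) == 0L) {
    bonds <- tibble(i = integer(), j = integer(), order = integer())
  } else {
    ii <- pmin(as.integer(bonds$i), as.integer(bonds$j))
    jj <- pmax(as.integer(bonds$i), as.integer(bonds$j))
    bonds <- tibble(i = ii, j = jj, order = as.integer(bonds$order)) |>
      arrange(.data$i, .data$j)
  }
  m <- structure(list(atoms = atoms, bonds = bonds), class = "constitution")
  if (validate) validate_constitution(m)
  m
}

#' @export
print.constitution <- function(x, ...) {
  cat("<constitution>", format_formula(constitution_formula(x)),
      "|", nrow(x$atoms), "heavy atoms,", nrow(x$bonds), "bonds\n")
  invisible(x)
}

n_atoms <- function(m) nrow(m$atoms)

#' Validate a constitution
#'
#' Checks the structural invariants: bond indices in range with no duplicate or
#' self bonds, exact valence conservation per atom (bond-order sum + implicit H
#' + |charge| equals the element's standard valence), and connectivity of the
#' heavy-atom graph.
#'
#' @param m A `constitution`.
#' @return `m`, invisibly; aborts with class `nmrcase_invalid_constitution`
#'   on violation.
#' @export
validate_constitution <- function(m) {
  a <- m$atoms; b <- m$bonds
  n <- nrow(a)
  if (n < 1L) abort("constitution needs at least one atom",
                    class = "nmrcase_invalid_constitution")
  if (nrow(b) > 0) {
    if (any(b$i < 1L | b$j > n | b$i >= b$j)) {
      abort("bond indices out of range or self-bond",
            class = "nmrcase_invalid_constitution")
    }
    if (anyDuplicated(b[c("i", "j")])) {
      abort("duplicate bond between the same atom pair",
            class = "nmrcase_invalid_constitution")
    }
    if (!all(b$order %in% 1:3)) {
      abort("bond orders must be 1, 2 or 3",
            class = "nmrcase_invalid_constitution")
    }
  }
  deg <- bond_order_sums(m)
  need <- valence_of(a$element) - abs(a$charge)
  bad <- which(deg + a$n_h != need)
  if (length(bad) > 0) {
    abort(paste0(
      "valence violated at atom ", bad[1], " (", a$element[bad[1]], "): ",
      "bond orders ", deg[bad[1]], " + H", a$n_h[bad[1]],
      " != ", need[bad[1]]
    ), class = "nmrcase_invalid_constitution")
  }
  if (!is_connected_graph(n, b)) {
    abort("constitution graph is not connected",
          class = "nmrcase_invalid_constitution")
  }
  invisible(m)
}

# Per-atom sum of bond orders.
bond_order_sums <- function(m) {
  n <- n_atoms(m)
  deg <- integer(n)
  if (nrow(m$bonds) > 0) {
    for (k in seq_len(nrow(m$bonds))) {
      deg[m$bonds$i[k]] <- deg[m$bonds$i[k]] + m$bonds$order[k]
      deg[m$bonds$j[k]] <- deg[m$bonds$j[k]] + m$bonds$order[k]
    }
  }
  deg
}

is_connected_graph <- function(n, bonds) {
  if (n == 1L) return(TRUE)
  if (nrow(bonds) < n - 1L) return(FALSE)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  adj <- adjacency_list(n, bonds)
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
    }
  }
  all(seen)
}

adjacency_list <- function(n, bonds) {
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- integer()
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
      adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
    }
  }
  adj
}

#' Molecular formula of a constitution
#'
#' @param m A `constitution`.
#' @return A `mol_formula` count vector including hydrogen.
#' @export
constitution_formula <- function(m) {
  counts <- table(m$atoms$element)
  out <- stats::setNames(as.integer(counts), names(counts))
  h <- sum(m$atoms$n_h)
  if (h > 0) out <- c(out, H = h)
  el <- names(out)
  ord <- c(intersect(c("C", "H"), el), sort(setdiff(el, c("C", "H"))))
  structure(out[ord], class = "mol_formula")
}

#' Number of rings plus multiple bonds in a constitution
#'
#' Equals `bonds - atoms + 1` (independent rings) plus the sum of
#' `order - 1` over all bonds; for any valence-legal connected constitution
#' this matches `dbe(constitution_formula(m))`.
#'
#' @param m A `constitution`.
#' @return Integer degree of unsaturation realised by the graph.
#' @export
graph_dbe <- function(m) {
  rings <- nrow(m$bonds) - n_atoms(m) + 1L
  rings + sum(m$bonds$order - 1L)
}

as_igraph <- function(m) {
  igraph::graph_from_data_frame(
    d = if (nrow(m$bonds) > 0) m$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(m)))
  )
}

# Aromatic bond perception, deliberately scoped to the classic benzenoid case:
# a six-membered ring of C/N atoms whose ring bonds alternate single/double is
# flagged aromatic so the two Kekule forms collapse to one canonical key and
# one environment key. Returns a logical vector parallel to m$bonds.
aromatic_bond_flags <- function(m) {
  nb <- nrow(m$bonds)
  flags <- logical(nb)
  if (nb < 6L) return(flags)
  bond_index <- function(u, v) {
    which(m$bonds$i == min(u, v) & m$bonds$j == max(u, v))
  }
  g <- as_igraph(m)
  for (k in seq_len(nb)) {
    u <- m$bonds$i[k]; v <- m$bonds$j[k]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = u, to = v, output = "vpath")$vpath[[1]]
    )
    ring <- as.integer(sp)
    if (length(ring) != 6L) next
    if (!all(m$atoms$element[ring] %in% c("C", "N"))) next
    cyc <- c(ring, ring[1])
    orders <- vapply(seq_len(6L), function(t) {
      m$bonds$order[bond_index(cyc[t], cyc[t + 1])]
    }, integer(1))
    if (all(sort(unique(orders)) == c(1L, 2L)) &&
        all(abs(diff(c(orders, orders[1]))) == 1L)) {
      for (t in seq_len(6L)) flags[bond_index(cyc[t], cyc[t + 1])] <- TRUE
    }
  }
  flags
}

# Bond orders with aromatic bonds replaced by the token 4 ("a" when rendered);
# shared by canonical keys and environment keys.
normalized_bond_orders <- function(m) {
  ord <- m$bonds$order
  ord[aromatic_bond_flags(m)] <- 4L
  ord
}

#' Size of the smallest ring in a constitution
#'
#' @param m A `constitution`.
#' @return Integer girth of the heavy-atom graph, or `Inf` if acyclic.
#' @export
smallest_ring_size <- function(m) {
  if (nrow(m$bonds) < n_atoms(m)) return(Inf)
  g <- igraph::girth(as_igraph(m))$girth
  if (is.null(g) || length(g) == 0 || g == 0) Inf else as.numeric(g)
}
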