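# NMR correlation lists -> bond-path-length constraints between heavy atoms.
#
# COSY cross peaks are vicinal 3J(H,H): the two H-bearing heavy atoms are
# bonded (path length 1). HMBC (13C or 15N) is 2-3 bond H -> X, which is
# ambiguous between heavy-atom path lengths 1 and 2 -- the central difficulty
# of CASE. 1,1-ADEQUATE gives one-bond C-C connectivity.

#' Build an atom-specification table
#'
#' One row per NMR-observed heavy atom: its label, element, chemical shift,
#' attached-proton count (from HSQC/DEPT) and hybridization (`"sp3"`,
#' `"sp2"`, `"sp"` or `"open"` when the bonding state is to be enumerated).
#'
#' @param id Character labels, unique.
#' @param element `"C"` or `"N"`.
#' @param n_h Integer 0-3 attached protons; `NA` leaves the count open.
#' @param hybridization One of `"sp3"`, `"sp2"`, `"sp"`, `"open"`.
#' @param shift_ppm Optional chemical shifts (ppm, >= 0).
#' @return A tibble of class `atom_specs`.
#' @export
atom_specs <- function(id, element, n_h, hybridization = "open",
                       shift_ppm = NA_real_) {
  out <- tibble(
    id = as.character(id), element = as.character(element),
    shift_ppm = as.numeric(shift_ppm), n_h = as.integer(n_h),
    hybridization = tolower(as.character(hybridization))
  )
  class(out) <- c("atom_specs", class(out))
  validate_atom_specs(out)
}

validate_atom_specs <- function(atoms) {
  atoms <- as_tibble(atoms)
  if (anyDuplicated(atoms$id)) {
    abort(paste0("duplicate atom id(s): ",
                 paste(unique(atoms$id[duplicated(atoms$id)]), collapse = ", ")),
          class = "nmrcase_input_error")
  }
  if (!all(atoms$element %in% c("C", "N"))) {
    abort("NMR-observed atoms must be C or N", class = "nmrcase_input_error")
  }
  if (!all(atoms$hybridization %in% c("sp3", "sp2", "sp", "open"))) {
    abort("hybridization must be sp3, sp2, sp or open",
          class = "nmrcase_input_error")
  }
  # full valence allowed so a lone-carbon methane input is expressible; in any
  # multi-atom molecule the generator rejects atoms left with no free valence
  max_h <- valence_of(atoms$element)
  bad <- which(!is.na(atoms$n_h) & (atoms$n_h < 0L | atoms$n_h > max_h))
  if (length(bad) > 0) {
    abort(paste0("n_h out of range for atom ", atoms$id[bad[1]]),
          class = "nmrcase_input_error")
  }
  if (any(!is.na(atoms$shift_ppm) & atoms$shift_ppm < 0)) {
    abort("chemical shifts must be >= 0", class = "nmrcase_input_error")
  }
  atoms
}

as_pair_tibble <- function(x, what) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) || length(x) == 0) {
    return(tibble(a = character(), b = character()))
  }
  if (is.matrix(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.list(x) && !is.data.frame(x)) {
    x <- as.data.frame(do.call(rbind, lapply(x, as.character)),
                       stringsAsFactors = FALSE)
  }
  if (ncol(x) != 2L) {
    abort(paste0(what, " correlations must be pairs of atom ids"),
          class = "nmrcase_input_error")
  }
  tibble(a = as.character(x[[1]]), b = as.character(x[[2]]))
}

#' Assemble a 2D-NMR correlation set
#'
#' @param cosy Pairs (id, id) of H-bearing heavy atoms showing vicinal H-H
#'   cross peaks.
#' @param hmbc Pairs (carbon id, H-bearing atom id) from 13C-HMBC.
#' @param n15hmbc Pairs (nitrogen id, H-bearing atom id) from 15N-HMBC.
#' @param adequate11 Pairs (carbon id, H-bearing carbon id) from
#'   1,1-ADEQUATE.
#'
#'   Each argument accepts a 2-column data frame/matrix or a list of length-2
#'   vectors.
#' @return A list of class `correlation_set` with tibble components.
#' @export
correlation_set <- function(cosy = NULL, hmbc = NULL, n15hmbc = NULL,
                            adequate11 = NULL) {
  structure(list(
    cosy = as_pair_tibble(cosy, "COSY"),
    hmbc = as_pair_tibble(hmbc, "HMBC"),
    n15hmbc = as_pair_tibble(n15hmbc, "15N-HMBC"),
    adequate11 = as_pair_tibble(adequate11, "1,1-ADEQUATE")
  ), class = "correlation_set")
}

#' @export
print.correlation_set <- function(x, ...) {
  cat("<correlation_set> COSY:", nrow(x$cosy), "| HMBC:", nrow(x$hmbc),
      "| 15N-HMBC:", nrow(x$n15hmbc), "| 1,1-ADEQUATE:", nrow(x$adequate11),
      "\n")
  invisible(x)
}

check_endpoint <- function(ids, atoms, need_h, what) {
  missing_ids <- setdiff(ids, atoms$id)
  if (length(missing_ids) > 0) {
    abort(paste0(what, " correlation names unknown atom id '",
                 missing_ids[1], "'"), class = "nmrcase_input_error")
  }
  if (length(need_h) > 0) {
    nh <- atoms$n_h[match(need_h, atoms$id)]
    bad <- which(!is.na(nh) & nh == 0L)
    if (length(bad) > 0) {
      abort(paste0(what, " correlation requires protons on atom '",
                   need_h[bad[1]], "' but its n_h is 0"),
            class = "nmrcase_input_error")
    }
  }
  invisible(NULL)
}

#' Compile correlations into path-length constraints
#'
#' Translates each correlation into the set of heavy-atom bond-path lengths it
#' allows: COSY and 1,1-ADEQUATE give `{1}` (direct bond); 13C- and 15N-HMBC
#' give `{1, 2}` (the 2-bond/3-bond ambiguity). Multiple constraints on the
#' same unordered atom pair are intersected; an empty intersection is a
#' contradiction and aborts.
#'
#' @param correlations A `correlation_set`.
#' @param atoms An `atom_specs` table covering every id used.
#' @param allow_4bond Widen HMBC to `{1, 2, 3}` to admit 4-bond correlations
#'   (default FALSE: the standard 2/3-bond convention).
#' @return A tibble of class `path_constraints` with columns `a`, `b`
#'   (atom ids, `a < b` lexically) and `lengths` (list of allowed integer
#'   path lengths).
#' @export
compile_constraints <- function(correlations, atoms, allow_4bond = FALSE) {
  stopifnot(inherits(correlations, "correlation_set"))
  atoms <- validate_atom_specs(atoms)
  hmbc_lengths <- if (allow_4bond) 1:3 else 1:2
  rows <- list()
  add <- function(a, b, lengths, what) {
    if (length(a) == 0L) return()
    self <- which(a == b)
    if (length(self) > 0) {
      abort(paste0(what, " correlation pairs atom '", a[self[1]],
                   "' with itself (geminal peaks carry no heavy-atom ",
                   "connectivity)"), class = "nmrcase_input_error")
    }
    lo <- pmin(a, b); hi <- pmax(a, b)
    rows[[length(rows) + 1L]] <<- tibble(
      a = lo, b = hi,
      lengths = replicate(length(a), as.integer(lengths), simplify = FALSE),
      source = what
    )
  }
  co <- correlations$cosy
  check_endpoint(c(co$a, co$b), atoms, c(co$a, co$b), "COSY")
  add(co$a, co$b, 1L, "COSY")
  hm <- correlations$hmbc
  check_endpoint(c(hm$a, hm$b), atoms, hm$b, "HMBC")
  add(hm$a, hm$b, hmbc_lengths, "HMBC")
  nh <- correlations$n15hmbc
  check_endpoint(c(nh$a, nh$b), atoms, nh$b, "15N-HMBC")
  add(nh$a, nh$b, hmbc_lengths, "15N-HMBC")
  ad <- correlations$adequate11
  check_endpoint(c(ad$a, ad$b), atoms, ad$b, "1,1-ADEQUATE")
  add(ad$a, ad$b, 1L, "1,1-ADEQUATE")
  if (length(rows) == 0L) {
    out <- tibble(a = character(), b = character(), lengths = list())
  } else {
    out <- bind_rows(rows) |>
      group_by(.data$a, .data$b) |>
      summarise(lengths = list(Reduce(intersect, .data$lengths)),
                .groups = "drop") |>
      arrange(.data$a, .data$b)
    empty <- which(lengths(out$lengths) == 0L)
    if (length(empty) > 0) {
      abort(paste0("contradictory correlations for atom pair (",
                   out$a[empty[1]], ", ", out$b[empty[1]], ")"),
            class = "nmrcase_contradiction_error")
    }
  }
  class(out) <- c("path_constraints", class(out))
  out
}

# TRUE iff a simple path of exactly len bonds joins u and v.
has_simple_path <- function(adj, u, v, len) {
  if (len == 1L) return(v %in% adj[[u]])
  if (len == 2L) {
    return(any(vapply(adj[[u]], function(w) {
      w != v && v %in% adj[[w]]
    }, logical(1))))
  }
  for (x in adj[[u]]) {
    if (x == v) next
    for (y in adj[[x]]) {
      if (y == u || y == v || y == x) next
      if (v %in% adj[[y]]) return(TRUE)
    }
  }
  FALSE
}

#' Check a constitution against path constraints
#'
#' A constraint is satisfied when *some* simple path of an allowed length
#' joins the two atoms -- in cyclic molecules a short and a longer relation
#' can coexist, so demanding that the shortest path be allowed would
#' over-constrain. Paths may run through NMR-silent heteroatoms.
#'
#' @param m A `constitution` whose atoms carry the constrained ids.
#' @param constraints A `path_constraints` tibble.
#' @return `TRUE`, or `FALSE` carrying the first violated constraint in
#'   attribute `violation` (a one-row tibble).
#' @export
check_satisfies <- function(m, constraints) {
  if (nrow(constraints) == 0L) return(TRUE)
  idx_a <- match(constraints$a, m$atoms$id)
  idx_b <- match(constraints$b, m$atoms$id)
  if (anyNA(idx_a) || anyNA(idx_b)) {
    missing_ids <- unique(c(constraints$a[is.na(idx_a)],
                            constraints$b[is.na(idx_b)]))
    abort(paste0("constraint id(s) not present in constitution: ",
                 paste(missing_ids, collapse = ", ")),
          class = "nmrcase_input_error")
  }
  adj <- adjacency_list(n_atoms(m), m$bonds)
  for (k in seq_len(nrow(constraints))) {
    ok <- any(vapply(constraints$lengths[[k]], function(L) {
      has_simple_path(adj, idx_a[k], idx_b[k], L)
    }, logical(1)))
    if (!ok) {
      res <- FALSE
      attr(res, "violation") <- constraints[k, ]
      return(res)
    }
  }
  TRUE
}
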