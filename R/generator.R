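# Exhaustive enumeration of constitutions compatible with formula, atom specs
# and path constraints.
#
# Strategy: depth-first assignment of a bond order (0-3) to every heavy-atom
# pair in a fixed lexicographic order, with constraint propagation -- {1}
# constraints are mandatory edges, remaining-valence and multiple-bond-pattern
# feasibility are checked as soon as an atom's pairs are exhausted, and
# forward capacity bounds prune dead branches early. Leaves are checked for
# connectivity, minimum ring size and the full constraint set, then
# deduplicated by canonical key. A naive generate-then-filter oracle
# (brute_force_enumerate) provides an independent check of completeness.

#' Generation configuration
#'
#' @param open_types Ignore the per-atom hybridizations in the input and
#'   enumerate all bonding states for every observed atom (the "no atom types
#'   defined" mode). Default FALSE: use the hybridizations given, which may
#'   individually be `"open"`.
#' @param min_ring_size Smallest ring allowed in generated structures
#'   (default 3, i.e. every chemically expressible ring).
#' @param max_results Cap on distinct constitutions; when hit, the result is
#'   flagged truncated rather than silently cut.
#' @param forbid_hetero_hetero Disallow bonds between two non-carbon heavy
#'   atoms (default FALSE: peroxide- and hydrazine-like motifs are left to
#'   the statistical filter, not the generator).
#' @param allow_charged Permit formally charged atoms (reserved; the
#'   generator currently builds neutral molecules only).
#' @return A list of class `generation_config`.
#' @export
generation_config <- function(open_types = FALSE, min_ring_size = 3L,
                              max_results = 1e6, forbid_hetero_hetero = FALSE,
                              allow_charged = FALSE) {
  stopifnot(min_ring_size >= 3L, max_results >= 1)
  structure(list(
    open_types = isTRUE(open_types),
    min_ring_size = as.integer(min_ring_size),
    max_results = max_results,
    forbid_hetero_hetero = isTRUE(forbid_hetero_hetero),
    allow_charged = isTRUE(allow_charged)
  ), class = "generation_config")
}

# ---- shared setup -----------------------------------------------------------

# Resolve formula + atom specs into the full heavy-atom table (observed atoms
# first, then NMR-silent heteroatoms) and the pool of hydrogens left to
# distribute. Errors are raised here, before any search starts.
generation_setup <- function(formula, atoms, config) {
  if (is.character(formula)) formula <- parse_formula(formula)
  dbe_f <- dbe(formula)  # also validates H parity
  atoms <- validate_atom_specs(atoms)
  counts <- stats::setNames(as.integer(formula), names(formula))
  obs_counts <- table(atoms$element)
  for (el in names(obs_counts)) {
    if ((counts[el] %||% 0L) < obs_counts[[el]]) {
      abort(paste0("more observed ", el, " atoms than the formula provides"),
            class = "nmrcase_infeasible_error")
    }
  }
  silent <- counts
  silent["H"] <- 0L
  for (el in names(obs_counts)) silent[el] <- silent[el] - obs_counts[[el]]
  silent <- silent[silent > 0L]
  valence_of(names(silent))  # errors on unsupported elements
  silent_tbl <- if (length(silent) > 0) {
    bind_rows(lapply(names(silent), function(el) {
      tibble(id = paste0(el, "*", seq_len(silent[[el]])), element = el,
             n_h = NA_integer_, hybridization = "silent")
    }))
  } else {
    tibble(id = character(), element = character(), n_h = integer(),
           hybridization = character())
  }
  hyb <- if (config$open_types) rep("open", nrow(atoms)) else
    atoms$hybridization
  all_atoms <- bind_rows(
    tibble(id = atoms$id, element = atoms$element, n_h = atoms$n_h,
           hybridization = hyb),
    silent_tbl
  )
  h_total <- counts["H"] %||% 0L
  h_fixed <- sum(all_atoms$n_h, na.rm = TRUE)
  if (h_fixed > h_total) {
    abort(paste0("atom specs fix ", h_fixed, " protons but the formula has ",
                 h_total), class = "nmrcase_infeasible_error")
  }
  open_h <- which(is.na(all_atoms$n_h))
  if (length(open_h) == 0L && h_fixed < h_total) {
    abort("leftover hydrogens but no silent or open-count atoms to carry them",
          class = "nmrcase_infeasible_error")
  }
  list(atoms = all_atoms, leftover_h = as.integer(h_total - h_fixed),
       open_h = open_h, dbe = dbe_f)
}

# All ways to distribute `total` hydrogens over the open positions, bounded
# per position by the element valence (minus one bonding valence when the
# molecule has more than one heavy atom).
h_distributions <- function(atoms, open_h, total) {
  n <- nrow(atoms)
  caps <- valence_of(atoms$element[open_h]) - (if (n > 1L) 1L else 0L)
  out <- list()
  recurse <- function(pos, left, acc) {
    if (pos > length(open_h)) {
      if (left == 0L) out[[length(out) + 1L]] <<- acc
      return()
    }
    hi <- min(caps[pos], left)
    for (h in 0:hi) recurse(pos + 1L, left - h, c(acc, h))
  }
  recurse(1L, total, integer(0))
  lapply(out, function(hs) {
    n_h <- atoms$n_h
    n_h[open_h] <- as.integer(hs)
    n_h
  })
}

# Multiple-bond pattern checks derived from hybridization: d = number of
# double bonds at the atom, t = number of triples.
pattern_ok_final <- function(hyb, d, t) {
  switch(hyb,
    sp3 = d == 0L && t == 0L,
    sp2 = d == 1L && t == 0L,
    sp  = (d == 0L && t == 1L) || (d == 2L && t == 0L),
    TRUE  # open / silent: any valence-legal pattern
  )
}

pattern_ok_partial <- function(hyb, d, t) {
  switch(hyb,
    sp3 = d == 0L && t == 0L,
    sp2 = d <= 1L && t == 0L,
    sp  = t <= 1L && d <= 2L && !(d > 0L && t > 0L),
    TRUE
  )
}

max_order_for <- function(hyb) {
  switch(hyb, sp3 = 1L, sp2 = 2L, 3L)
}

# Pair bookkeeping shared by both search paths.
pair_table <- function(n) {
  if (n < 2L) return(list(pi = integer(0), pj = integer(0)))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  list(pi = idx[ord, 1], pj = idx[ord, 2])
}

new_result_store <- function(config) {
  env <- new.env(parent = emptyenv())
  env$keys <- character(0)
  env$constitutions <- list()
  env$truncated <- FALSE
  env$n_leaves <- 0L
  env$config <- config
  env
}

store_add <- function(store, m) {
  key <- canonical_key(m)
  if (key %in% store$keys) return(invisible(FALSE))
  if (length(store$keys) >= store$config$max_results) {
    store$truncated <- TRUE
    return(invisible(FALSE))
  }
  store$keys <- c(store$keys, key)
  store$constitutions[[length(store$constitutions) + 1L]] <- m
  invisible(TRUE)
}

leaf_accept <- function(atoms, n_h, bonds, config, constraints, store) {
  store$n_leaves <- store$n_leaves + 1L
  m <- constitution(
    atoms = tibble(id = atoms$id, element = atoms$element, charge = 0L,
                   n_h = n_h),
    bonds = bonds, validate = FALSE
  )
  if (!is_connected_graph(nrow(atoms), bonds)) return(invisible(FALSE))
  if (config$min_ring_size > 3L &&
      smallest_ring_size(m) < config$min_ring_size) {
    return(invisible(FALSE))
  }
  if (!isTRUE(check_satisfies(m, constraints))) return(invisible(FALSE))
  store_add(store, m)
}

candidate_set_result <- function(store, setup, config, constraints) {
  out <- structure(list(
    constitutions = store$constitutions,
    keys = store$keys,
    meta = list(
      config = config,
      n_constraints = nrow(constraints),
      n_heavy = nrow(setup$atoms),
      truncated = store$truncated
    )
  ), class = "candidate_set")
  for (m in out$constitutions) {
    stopifnot(graph_dbe(m) == setup$dbe)  # dbe consistency invariant
  }
  out
}

empty_constraints <- function() {
  out <- tibble(a = character(), b = character(), lengths = list())
  class(out) <- c("path_constraints", class(out))
  out
}

#' Enumerate all constitutions compatible with NMR evidence
#'
#' Generates every isomorphism class of connected molecular graph that
#' matches the molecular formula and valences, realises the fixed per-atom
#' proton counts (leftover hydrogens are distributed exhaustively over silent
#' heteroatoms and open-count positions), respects hybridizations (fixed or
#' enumerated), and satisfies every compiled path constraint. Results are
#' deduplicated by canonical key and independent of atom input order.
#'
#' @param formula A `mol_formula` or Hill-notation string.
#' @param atoms An `atom_specs` table of the NMR-observed heavy atoms.
#' @param constraints A `path_constraints` tibble from
#'   [compile_constraints()]; `NULL` for an unconstrained run.
#' @param config A [generation_config()].
#' @return A `candidate_set`: constitutions, canonical keys and run metadata.
#' @examples
#' at <- atom_specs(c("C1", "C2"), "C", c(3, 2), "sp3")
#' cs <- compile_constraints(correlation_set(cosy = list(c("C1", "C2"))), at)
#' enumerate_constitutions("C2H6O", at, cs)
#' @export
enumerate_constitutions <- function(formula, atoms, constraints = NULL,
                                    config = generation_config()) {
  if (is.null(constraints)) constraints <- empty_constraints()
  setup <- generation_setup(formula, atoms, config)
  at <- setup$atoms
  n <- nrow(at)
  id_index <- stats::setNames(seq_len(n), at$id)
  # mandatory edges from {1}-constraints
  mand <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(constraints))) {
    if (identical(constraints$lengths[[k]], 1L)) {
      ia <- id_index[[constraints$a[k]]]
      ib <- id_index[[constraints$b[k]]]
      mand[ia, ib] <- mand[ib, ia] <- TRUE
    }
  }
  mand_deg <- rowSums(mand)
  rem_max <- valence_of(at$element) -
    ifelse(is.na(at$n_h), 0L, at$n_h)
  if (any(mand_deg > rem_max)) {
    abort(paste0("required direct bonds exceed the free valence of atom '",
                 at$id[which(mand_deg > rem_max)[1]], "'"),
          class = "nmrcase_infeasible_error")
  }
  pt <- pair_table(n)
  npairs <- length(pt$pi)
  # for capacity pruning: pairs involving atom v at position > k
  future_pairs <- matrix(0L, n, npairs + 1L)
  if (npairs > 0) {
    for (k in npairs:1) {
      future_pairs[, k] <- future_pairs[, k + 1L]
      future_pairs[pt$pi[k], k] <- future_pairs[pt$pi[k], k] + 1L
      future_pairs[pt$pj[k], k] <- future_pairs[pt$pj[k], k] + 1L
    }
  }
  is_hetero <- !(at$element %in% c("C"))
  hyb <- at$hybridization
  maxord <- vapply(hyb, max_order_for, integer(1))
  store <- new_result_store(config)
  for (n_h in h_distributions(at, setup$open_h, setup$leftover_h)) {
    rem0 <- valence_of(at$element) - n_h
    if (n > 1L && any(rem0 < 1L)) next
    if (any(rem0 < mand_deg)) next
    if (sum(rem0) %% 2L != 0L) next
    orders <- integer(npairs)
    dd <- integer(n); tt <- integer(n)
    rem <- rem0
    recurse <- function(k) {
      if (store$truncated) return()
      if (k > npairs) {
        bonds <- tibble(i = pt$pi[orders > 0L], j = pt$pj[orders > 0L],
                        order = orders[orders > 0L])
        leaf_accept(at, n_h, bonds, config, constraints, store)
        return()
      }
      u <- pt$pi[k]; v <- pt$pj[k]
      choices <- 0:min(rem[u], rem[v], maxord[u], maxord[v])
      if (mand[u, v]) choices <- setdiff(choices, 0L)
      if (config$forbid_hetero_hetero && is_hetero[u] && is_hetero[v]) {
        choices <- intersect(choices, 0L)
      }
      for (o in choices) {
        if (o > 1L) {
          du <- dd[u] + (o == 2L); tu <- tt[u] + (o == 3L)
          dv <- dd[v] + (o == 2L); tv <- tt[v] + (o == 3L)
          if (!pattern_ok_partial(hyb[u], du, tu) ||
              !pattern_ok_partial(hyb[v], dv, tv)) next
        }
        orders[k] <<- o
        rem[u] <<- rem[u] - o; rem[v] <<- rem[v] - o
        if (o == 2L) { dd[u] <<- dd[u] + 1L; dd[v] <<- dd[v] + 1L }
        if (o == 3L) { tt[u] <<- tt[u] + 1L; tt[v] <<- tt[v] + 1L }
        ok <- TRUE
        # atom u finishes at its last pair (u, n)
        if (v == n) {
          ok <- rem[u] == 0L && pattern_ok_final(hyb[u], dd[u], tt[u])
          if (ok && u == n - 1L) {
            ok <- rem[n] == 0L && pattern_ok_final(hyb[n], dd[n], tt[n])
          }
        }
        if (ok) {
          # capacity: every unfinished atom must still be able to spend rem
          ok <- all(rem <= maxord * future_pairs[, k + 1L])
        }
        if (ok) recurse(k + 1L)
        orders[k] <<- 0L
        rem[u] <<- rem[u] + o; rem[v] <<- rem[v] + o
        if (o == 2L) { dd[u] <<- dd[u] - 1L; dd[v] <<- dd[v] - 1L }
        if (o == 3L) { tt[u] <<- tt[u] - 1L; tt[v] <<- tt[v] - 1L }
      }
    }
    if (npairs == 0L) {
      if (rem0[1] == 0L) {
        leaf_accept(at, n_h, tibble(i = integer(), j = integer(),
                                    order = integer()),
                    config, constraints, store)
      }
    } else {
      recurse(1L)
    }
  }
  candidate_set_result(store, setup, config, constraints)
}

#' Naive generate-then-filter enumeration (independent oracle)
#'
#' Enumerates *all* valence-legal bond-order assignments over every heavy-atom
#' pair with no constraint propagation, then filters the leaves for
#' connectivity, hybridization patterns, ring size and path constraints.
#' Exponentially slower than [enumerate_constitutions()] but algorithmically
#' independent of it; refuses inputs above `limit` heavy atoms.
#'
#' @inheritParams enumerate_constitutions
#' @param limit Maximum heavy-atom count accepted (default 7).
#' @return A `candidate_set`.
#' @export
brute_force_enumerate <- function(formula, atoms, constraints = NULL,
                                  config = generation_config(), limit = 7L) {
  if (is.null(constraints)) constraints <- empty_constraints()
  if (is.character(formula)) formula <- parse_formula(formula)
  n_heavy <- sum(formula[names(formula) != "H"])
  if (n_heavy > limit) {
    abort(paste0("brute-force oracle refuses ", n_heavy,
                 " heavy atoms (limit ", limit, ")"),
          class = "nmrcase_oracle_limit_error")
  }
  setup <- generation_setup(formula, atoms, config)
  at <- setup$atoms
  n <- nrow(at)
  pt <- pair_table(n)
  npairs <- length(pt$pi)
  store <- new_result_store(config)
  hyb <- at$hybridization
  is_hetero <- !(at$element %in% c("C"))
  leaf_filter <- function(n_h, orders) {
    # every check happens here, at the leaf -- no propagation
    dd <- integer(n); tt <- integer(n)
    for (k in which(orders > 0L)) {
      if (orders[k] == 2L) {
        dd[pt$pi[k]] <- dd[pt$pi[k]] + 1L; dd[pt$pj[k]] <- dd[pt$pj[k]] + 1L
      }
      if (orders[k] == 3L) {
        tt[pt$pi[k]] <- tt[pt$pi[k]] + 1L; tt[pt$pj[k]] <- tt[pt$pj[k]] + 1L
      }
      if (config$forbid_hetero_hetero &&
          is_hetero[pt$pi[k]] && is_hetero[pt$pj[k]]) return()
    }
    for (v in seq_len(n)) {
      if (!pattern_ok_final(hyb[v], dd[v], tt[v])) return()
    }
    bonds <- tibble(i = pt$pi[orders > 0L], j = pt$pj[orders > 0L],
                    order = orders[orders > 0L])
    leaf_accept(at, n_h, bonds, config, constraints, store)
  }
  for (n_h in h_distributions(at, setup$open_h, setup$leftover_h)) {
    rem0 <- valence_of(at$element) - n_h
    if (sum(rem0) %% 2L != 0L) next
    orders <- integer(npairs)
    rem <- rem0
    recurse <- function(k) {
      if (k > npairs) {
        if (all(rem == 0L)) leaf_filter(n_h, orders)
        return()
      }
      u <- pt$pi[k]; v <- pt$pj[k]
      for (o in 0:min(rem[u], rem[v], 3L)) {
        orders[k] <<- o
        rem[u] <<- rem[u] - o; rem[v] <<- rem[v] - o
        recurse(k + 1L)
        orders[k] <<- 0L
        rem[u] <<- rem[u] + o; rem[v] <<- rem[v] + o
      }
    }
    if (npairs == 0L) {
      if (rem0[1] == 0L) leaf_filter(n_h, integer(0))
    } else {
      recurse(1L)
    }
  }
  candidate_set_result(store, setup, config, constraints)
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set>", length(x$keys), "constitution(s)",
      if (isTRUE(x$meta$truncated)) "[TRUNCATED]" else "", "\n")
  invisible(x)
}

#' @rdname candidate_set_tidiers
#' @method tidy candidate_set
#' @export
tidy.candidate_set <- function(x, ...) {
  if (length(x$constitutions) == 0L) {
    return(tibble(smiles = character(), key = character(),
                  n_heavy = integer(), n_rings = integer()))
  }
  tibble(
    smiles = as_smiles(x$constitutions),
    key = x$keys,
    n_heavy = vapply(x$constitutions, n_atoms, integer(1)),
    n_rings = vapply(x$constitutions, function(m) {
      nrow(m$bonds) - n_atoms(m) + 1L
    }, integer(1))
  )
}

#' Tidiers for candidate sets
#'
#' `tidy()` returns one row per generated constitution (canonical SMILES,
#' canonical key, heavy-atom and ring counts); `glance()` returns a one-row
#' run summary.
#'
#' @param x A `candidate_set`.
#' @param ... Unused.
#' @name candidate_set_tidiers
#' @method glance candidate_set
#' @export
glance.candidate_set <- function(x, ...) {
  tibble(
    n_constitutions = length(x$keys),
    n_heavy = x$meta$n_heavy,
    n_constraints = x$meta$n_constraints,
    truncated = isTRUE(x$meta$truncated)
  )
}
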