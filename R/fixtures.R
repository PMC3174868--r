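# Forward model and synthetic-data generators.
#
# forward_correlations() predicts the correlation set a known structure would
# show in COSY / HMBC / 15N-HMBC / 1,1-ADEQUATE experiments; together with
# seeded toy-structure and reference-corpus generators it closes the loop
# that makes every stage testable without external data: a structure's own
# dropout-free correlations must always regenerate a candidate set containing
# that structure.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Forward-model configuration
#'
#' @param experiments Subset of `"cosy"`, `"hmbc"`, `"n15hmbc"`,
#'   `"adequate11"`; which correlation lists to simulate.
#' @param hmbc_lengths H-to-heavy-atom bond-path lengths an HMBC cross peak
#'   spans (default `c(2, 3)`, the standard 2/3-bond convention;
#'   heavy-atom path lengths are one less).
#' @param dropout Probability in `[0, 1)` of omitting each correlation
#'   independently, modelling sparse experimental data (default 0).
#' @param seed Integer seed controlling dropout reproducibly.
#' @return A list of class `forward_config`.
#' @export
forward_config <- function(experiments = c("cosy", "hmbc"),
                           hmbc_lengths = c(2L, 3L), dropout = 0,
                           seed = 1L) {
  experiments <- match.arg(tolower(experiments),
                           c("cosy", "hmbc", "n15hmbc", "adequate11"),
                           several.ok = TRUE)
  stopifnot(length(experiments) > 0, dropout >= 0, dropout < 1)
  structure(list(
    experiments = experiments,
    hmbc_lengths = as.integer(hmbc_lengths),
    dropout = dropout,
    seed = as.integer(seed)
  ), class = "forward_config")
}

# Assign NMR-style ids (C1, C2, ..., N1, ..., O*1, ...) to atoms lacking them.
label_atoms <- function(m) {
  if (!anyNA(m$atoms$id) && !anyDuplicated(m$atoms$id)) return(m)
  ids <- character(n_atoms(m))
  for (el in unique(m$atoms$element)) {
    at <- which(m$atoms$element == el)
    sep <- if (el %in% c("C", "N")) "" else "*"
    ids[at] <- paste0(el, sep, seq_along(at))
  }
  m$atoms$id <- ids
  m
}

#' Derive atom specifications from a known structure
#'
#' Extracts the NMR-observed atoms (C and N) of a constitution as an
#' `atom_specs` table: H counts as HSQC/DEPT would report them, and
#' hybridization read off the bond pattern (a triple or two doubles is sp,
#' one double is sp2, otherwise sp3).
#'
#' @param m A `constitution`.
#' @return An `atom_specs` tibble.
#' @export
as_atom_specs <- function(m) {
  m <- label_atoms(m)
  obs <- which(m$atoms$element %in% c("C", "N"))
  hyb <- vapply(obs, function(v) {
    inc <- m$bonds$order[m$bonds$i == v | m$bonds$j == v]
    if (any(inc == 3L) || sum(inc == 2L) >= 2L) "sp"
    else if (any(inc == 2L)) "sp2"
    else "sp3"
  }, character(1))
  atom_specs(
    id = m$atoms$id[obs], element = m$atoms$element[obs],
    n_h = m$atoms$n_h[obs], hybridization = hyb
  )
}

#' Simulate the 2D-NMR correlation set of a known structure
#'
#' The forward model: COSY cross peaks for every bonded pair of H-bearing
#' observed atoms; HMBC (and 15N-HMBC) peaks for every carbon (nitrogen) and
#' H-bearing observed atom joined by a simple path whose H-to-heavy length is
#' in `hmbc_lengths`; 1,1-ADEQUATE peaks for every bonded carbon pair with a
#' protonated member. Dropout removes each correlation independently with the
#' configured probability, reproducibly under the configured seed.
#'
#' @param m A `constitution`.
#' @param config A [forward_config()].
#' @return A `correlation_set`; the labeled structure is carried in
#'   attribute `structure`.
#' @export
forward_correlations <- function(m, config = forward_config()) {
  m <- label_atoms(m)
  a <- m$atoms
  adj <- adjacency_list(n_atoms(m), m$bonds)
  observed <- which(a$element %in% c("C", "N"))
  h_bearing <- intersect(observed, which(a$n_h >= 1L))
  heavy_lengths <- sort(unique(config$hmbc_lengths - 1L))
  heavy_lengths <- heavy_lengths[heavy_lengths >= 1L]

  cosy <- list(); hmbc <- list(); n15 <- list(); adeq <- list()
  if ("cosy" %in% config$experiments) {
    for (k in seq_len(nrow(m$bonds))) {
      u <- m$bonds$i[k]; v <- m$bonds$j[k]
      if (u %in% h_bearing && v %in% h_bearing) {
        cosy[[length(cosy) + 1L]] <- c(a$id[u], a$id[v])
      }
    }
  }
  long_range <- function(centers) {
    out <- list()
    for (cc in centers) {
      for (h in h_bearing) {
        if (h == cc) next
        hit <- any(vapply(heavy_lengths, function(L) {
          has_simple_path(adj, cc, h, L)
        }, logical(1)))
        if (hit) out[[length(out) + 1L]] <- c(a$id[cc], a$id[h])
      }
    }
    out
  }
  if ("hmbc" %in% config$experiments) {
    hmbc <- long_range(which(a$element == "C"))
  }
  if ("n15hmbc" %in% config$experiments) {
    n15 <- long_range(which(a$element == "N"))
  }
  if ("adequate11" %in% config$experiments) {
    for (k in seq_len(nrow(m$bonds))) {
      u <- m$bonds$i[k]; v <- m$bonds$j[k]
      if (a$element[u] == "C" && a$element[v] == "C") {
        if (a$n_h[v] >= 1L) {
          adeq[[length(adeq) + 1L]] <- c(a$id[u], a$id[v])
        } else if (a$n_h[u] >= 1L) {
          adeq[[length(adeq) + 1L]] <- c(a$id[v], a$id[u])
        }
      }
    }
  }
  if (config$dropout > 0) {
    drop_some <- function(x) {
      if (length(x) == 0L) return(x)
      x[stats::runif(length(x)) >= config$dropout]
    }
    res <- with_seed_local(config$seed, {
      list(cosy = drop_some(cosy), hmbc = drop_some(hmbc),
           n15 = drop_some(n15), adeq = drop_some(adeq))
    })
    cosy <- res$cosy; hmbc <- res$hmbc; n15 <- res$n15; adeq <- res$adeq
  }
  out <- correlation_set(cosy = cosy, hmbc = hmbc, n15hmbc = n15,
                         adequate11 = adeq)
  attr(out, "structure") <- m
  out
}

# Grow one random connected valence-legal structure; NULL on a dead end.
random_structure <- function(n_heavy, element_probs) {
  elements <- c("C", sample(names(element_probs), n_heavy - 1L,
                            replace = TRUE, prob = element_probs))
  if (n_heavy == 1L) elements <- "C"
  free <- valence_of(elements)
  bi <- integer(0); bj <- integer(0); bo <- integer(0)
  for (v in seq_len(n_heavy)[-1]) {
    anchors <- which(free[seq_len(v - 1L)] >= 1L)
    if (length(anchors) == 0L) return(NULL)
    u <- if (length(anchors) == 1L) anchors else sample(anchors, 1L)
    bi <- c(bi, u); bj <- c(bj, v); bo <- c(bo, 1L)
    free[u] <- free[u] - 1L; free[v] <- free[v] - 1L
  }
  # occasional ring closure
  if (n_heavy >= 3L && stats::runif(1) < 0.3) {
    open <- which(free >= 1L)
    cand <- list()
    for (u in open) for (v in open) {
      if (u < v && !any(bi == u & bj == v)) cand[[length(cand) + 1L]] <- c(u, v)
    }
    if (length(cand) > 0) {
      pick <- cand[[sample.int(length(cand), 1L)]]
      bi <- c(bi, pick[1]); bj <- c(bj, pick[2]); bo <- c(bo, 1L)
      free[pick] <- free[pick] - 1L
    }
  }
  # occasional bond-order upgrades
  for (k in seq_along(bi)) {
    if (free[bi[k]] >= 1L && free[bj[k]] >= 1L && stats::runif(1) < 0.25) {
      up <- 1L
      if (free[bi[k]] >= 2L && free[bj[k]] >= 2L && stats::runif(1) < 0.3) {
        up <- 2L
      }
      bo[k] <- bo[k] + up
      free[bi[k]] <- free[bi[k]] - up
      free[bj[k]] <- free[bj[k]] - up
    }
  }
  m <- constitution(
    atoms = tibble(element = elements, charge = 0L, n_h = free),
    bonds = tibble(i = bi, j = bj, order = bo),
    validate = FALSE
  )
  tryCatch({ validate_constitution(m); label_atoms(m) },
           error = function(e) NULL)
}

#' Generate seeded toy structures
#'
#' Random connected, valence-legal constitutions with distinct canonical
#' keys, each containing at least one protonated carbon (so every structure
#' shows at least one correlation). Reproducible per seed.
#'
#' @param seed Integer seed.
#' @param n Number of structures.
#' @param heavy_atoms Length-2 integer range of heavy-atom counts; capped at
#'   7 so the brute-force oracle stays applicable.
#' @param element_probs Named sampling weights for non-initial atoms.
#' @return A list of `n` `constitution` objects.
#' @export
make_toy_structures <- function(seed, n, heavy_atoms = c(2L, 6L),
                                element_probs = c(C = 0.7, N = 0.15,
                                                  O = 0.15)) {
  stopifnot(n >= 1L, length(heavy_atoms) == 2L)
  if (max(heavy_atoms) > 7L) {
    abort("heavy_atoms range exceeds the brute-force oracle limit of 7",
          class = "nmrcase_input_error")
  }
  with_seed_local(seed, {
    out <- list(); keys <- character(0); tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 200L * n) {
        abort("could not generate enough distinct toy structures in range",
              class = "nmrcase_input_error")
      }
      nh <- sample(seq(heavy_atoms[1], heavy_atoms[2]), 1L)
      m <- random_structure(nh, element_probs)
      if (is.null(m)) next
      if (!any(m$atoms$element == "C" & m$atoms$n_h >= 1L)) next
      key <- canonical_key(m)
      if (key %in% keys) next
      keys <- c(keys, key)
      out[[length(out) + 1L]] <- m
    }
    out
  })
}

#' Generate a seeded reference corpus
#'
#' A desk-scale stand-in for a large corpus of known molecules: random small
#' structures biased toward common organic functional groups via
#' heteroatom-rich element weights. Duplicates are allowed (a corpus counts
#' occurrences).
#'
#' @param seed Integer seed.
#' @param n Number of molecules (must be >= 1; an empty corpus is refused
#'   downstream).
#' @param heavy_atoms Length-2 integer range of heavy-atom counts.
#' @param element_probs Named sampling weights for non-initial atoms.
#' @return A list of `n` `constitution` objects.
#' @export
make_reference_corpus <- function(seed, n, heavy_atoms = c(2L, 7L),
                                  element_probs = c(C = 0.55, N = 0.2,
                                                    O = 0.25)) {
  if (n < 1L) {
    abort("reference corpus size must be >= 1",
          class = "nmrcase_input_error")
  }
  stopifnot(length(heavy_atoms) == 2L, max(heavy_atoms) <= 7L)
  with_seed_local(seed + 10000L, {
    out <- list(); tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 500L * n) {
        abort("could not generate the requested corpus",
              class = "nmrcase_input_error")
      }
      nh <- sample(seq(heavy_atoms[1], heavy_atoms[2]), 1L)
      m <- random_structure(nh, element_probs)
      if (is.null(m)) next
      out[[length(out) + 1L]] <- m
    }
    out
  })
}
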