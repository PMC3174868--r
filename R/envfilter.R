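# The statistical filter: one-sphere (radius-1) atom environments.
#
# A candidate constitution is plausible only if every atom's immediate bonded
# neighborhood -- element, charge, H count, and the multiset of
# (neighbor element, bond order) pairs -- has been observed at least once in a
# reference corpus of known molecules. Candidates containing an unseen
# environment are eliminated; candidates whose environments are all covered
# are always kept, so a true structure whose chemistry is represented in the
# corpus can never be lost.

#' One-sphere environment key of an atom
#'
#' Renders the radius-1 environment of atom `i` as a deterministic string:
#' center element, formal charge, H count, then the neighbor
#' `(element, bond order)` multiset sorted by element and then bond order.
#' Bonds in six-membered alternating C/N rings use a dedicated aromatic token
#' so the two Kekule forms of such a ring yield identical keys.
#'
#' @param m A `constitution`.
#' @param i Atom index (1-based).
#' @return A single string, e.g. `"C H2 (C:1,O:1)"` rendered as
#'   `"CH2(C:1,O:1)"`.
#' @export
env_key <- function(m, i) {
  stopifnot(i >= 1L, i <= n_atoms(m))
  env_profile(m)[i]
}

#' All one-sphere environment keys of a constitution
#'
#' @param m A `constitution`.
#' @return Character vector, one key per atom (duplicates preserved).
#' @export
env_profile <- function(m) {
  orders <- normalized_bond_orders(m)
  n <- n_atoms(m)
  nb_el <- vector("list", n)
  nb_or <- vector("list", n)
  if (nrow(m$bonds) > 0) {
    for (k in seq_len(nrow(m$bonds))) {
      i <- m$bonds$i[k]; j <- m$bonds$j[k]
      nb_el[[i]] <- c(nb_el[[i]], m$atoms$element[j])
      nb_or[[i]] <- c(nb_or[[i]], orders[k])
      nb_el[[j]] <- c(nb_el[[j]], m$atoms$element[i])
      nb_or[[j]] <- c(nb_or[[j]], orders[k])
    }
  }
  vapply(seq_len(n), function(v) {
    el <- nb_el[[v]]; orr <- nb_or[[v]]
    nb <- if (length(el) > 0) {
      ord <- order(el, orr, method = "radix")
      paste0(el[ord], ":", order_token(orr[ord]), collapse = ",")
    } else ""
    paste0(
      m$atoms$element[v], charge_token(m$atoms$charge[v]), "H", m$atoms$n_h[v],
      "(", nb, ")"
    )
  }, character(1))
}

#' Build a reference environment dictionary from a corpus
#'
#' Every atom of every parsed corpus molecule contributes one count to its
#' environment key. The dictionary is the plausibility standard the
#' statistical filter checks candidates against.
#'
#' @param corpus A list of `constitution` objects, a character vector of
#'   SMILES, or a path to a SMILES file (one molecule per line; unparseable
#'   lines are skipped and counted).
#' @param source_name Free-text provenance recorded in the metadata.
#' @return A tibble of class `reference_dict` with columns `env_key` and
#'   `count`, sorted by key; corpus metadata in attribute `meta`.
#' @export
build_reference <- function(corpus, source_name = "corpus") {
  n_skipped <- 0L
  if (is.character(corpus) && length(corpus) == 1L && file.exists(corpus)) {
    source_name <- corpus
    corpus <- read_smiles_file(corpus)
    n_skipped <- attr(corpus, "n_skipped") %||% 0L
  } else if (is.character(corpus)) {
    corpus <- parse_smiles(corpus)
  } else if (inherits(corpus, "constitution")) {
    corpus <- list(corpus)
  }
  if (length(corpus) == 0L) {
    abort("reference corpus is empty after parsing; a filter built from an empty corpus would eliminate everything",
          class = "nmrcase_input_error")
  }
  keys <- unlist(lapply(corpus, env_profile))
  tab <- table(keys)
  out <- tibble(env_key = names(tab), count = as.integer(tab)) |>
    arrange(.data$env_key)
  attr(out, "meta") <- list(
    source = source_name,
    n_molecules = length(corpus),
    n_atoms = length(keys),
    n_skipped = n_skipped,
    built = format(Sys.time(), "%Y-%m-%d")
  )
  class(out) <- c("reference_dict", class(out))
  out
}

#' Write / read a reference dictionary as TSV
#'
#' Two columns (`env_key`, `count`) preceded by `#`-comment header lines
#' carrying the corpus metadata.
#'
#' @param ref A `reference_dict`.
#' @param path File path.
#' @return `write_reference()` returns `ref` invisibly; `read_reference()`
#'   returns a `reference_dict`.
#' @export
write_reference <- function(ref, path) {
  meta <- attr(ref, "meta") %||% list()
  hdr <- c(
    paste0("# source: ", meta$source %||% "unknown"),
    paste0("# n_molecules: ", meta$n_molecules %||% NA),
    paste0("# n_atoms: ", meta$n_atoms %||% NA),
    paste0("# built: ", meta$built %||% NA),
    "env_key\tcount"
  )
  writeLines(c(hdr, paste0(ref$env_key, "\t", ref$count)), path)
  invisible(ref)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("reference dictionary not found: ", path),
          class = "nmrcase_io_error")
  }
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) < 1L || body[1] != "env_key\tcount") {
    abort("malformed reference dictionary (missing 'env_key\\tcount' header)",
          class = "nmrcase_io_error")
  }
  parts <- strsplit(body[-1], "\t", fixed = TRUE)
  out <- tibble(
    env_key = vapply(parts, `[[`, character(1), 1),
    count = as.integer(vapply(parts, `[[`, character(1), 2))
  )
  grab <- function(field) {
    ln <- grep(paste0("^# ", field, ": "), meta_lines, value = TRUE)
    if (length(ln) > 0) sub(paste0("^# ", field, ": "), "", ln[1]) else NA
  }
  attr(out, "meta") <- list(
    source = grab("source"),
    n_molecules = suppressWarnings(as.integer(grab("n_molecules"))),
    n_atoms = suppressWarnings(as.integer(grab("n_atoms"))),
    built = grab("built")
  )
  class(out) <- c("reference_dict", class(out))
  out
}

#' Filter candidates by reference-environment coverage
#'
#' Keeps a candidate iff every one of its one-sphere environment keys occurs
#' in the reference dictionary (at least `min_count` times). Removed
#' candidates record all their missing keys. Input order is preserved in the
#' kept set. No ranking of survivors is performed.
#'
#' @param candidates A `candidate_set`, list of `constitution`s, character
#'   vector of SMILES, or a SMILES/SDF file path.
#' @param reference A `reference_dict` (or a path to one).
#' @param min_count Minimum corpus occurrences for a key to count as known
#'   (default 1: pure presence/absence).
#' @return A `filter_report`: `kept` (list of constitutions), `removed`
#'   (tibble with `smiles` and list-column `missing`), and `reduction`
#'   (fraction of candidates removed).
#' @export
filter_candidates <- function(candidates, reference, min_count = 1L) {
  if (is.character(reference)) reference <- read_reference(reference)
  if (nrow(reference) == 0L) {
    abort("reference dictionary is empty", class = "nmrcase_input_error")
  }
  ms <- as_constitution_list(candidates)
  known <- reference$env_key[reference$count >= min_count]
  missing <- lapply(ms, function(m) sort(setdiff(env_profile(m), known)))
  keep <- lengths(missing) == 0L
  removed_ms <- ms[!keep]
  report <- structure(list(
    kept = ms[keep],
    removed = tibble(
      smiles = if (length(removed_ms) > 0) as_smiles(removed_ms) else
        character(0),
      missing = missing[!keep]
    ),
    n_input = length(ms),
    reduction = if (length(ms) == 0) 0 else mean(!keep)
  ), class = "filter_report")
  report
}

as_constitution_list <- function(x) {
  if (inherits(x, "candidate_set")) return(x$constitutions)
  if (inherits(x, "constitution")) return(list(x))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (grepl("\\.sdf$", x, ignore.case = TRUE)) return(read_sdf(x))
    return(read_smiles_file(x))
  }
  if (is.character(x)) return(parse_smiles(x))
  stopifnot(is.list(x))
  x
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>", length(x$kept), "kept /", nrow(x$removed),
      sprintf("removed (reduction %.1f%%)", 100 * x$reduction), "\n")
  invisible(x)
}

#' Tabulate the environment keys that drove exclusions
#'
#' One row per missing environment key with the number of removed candidates
#' containing it, sorted by count (descending) then key (lexical) -- the
#' table a user reads to see which substructural element the filter rejected.
#'
#' @param report A `filter_report`.
#' @return A tibble with columns `env_key` and `n_candidates`.
#' @export
summarize_missing <- function(report) {
  stopifnot(inherits(report, "filter_report"))
  if (nrow(report$removed) == 0L) {
    return(tibble(env_key = character(), n_candidates = integer()))
  }
  report$removed |>
    mutate(missing = lapply(.data$missing, unique)) |>
    tidyr::unnest(cols = "missing") |>
    count(env_key = .data$missing, name = "n_candidates") |>
    arrange(desc(.data$n_candidates), .data$env_key)
}

#' @rdname filter_report_tidiers
#' @method tidy filter_report
#' @export
tidy.filter_report <- function(x, ...) {
  bind_rows(
    tibble(smiles = if (length(x$kept) > 0) as_smiles(x$kept) else character(0),
           status = "kept", n_missing = 0L),
    tibble(smiles = x$removed$smiles, status = "removed",
           n_missing = lengths(x$removed$missing))
  )
}

#' Tidiers for filter reports
#'
#' `tidy()` gives one row per candidate with its kept/removed status;
#' `glance()` gives the one-row summary (input size, kept, removed,
#' reduction fraction).
#'
#' @param x A `filter_report`.
#' @param ... Unused.
#' @name filter_report_tidiers
#' @method glance filter_report
#' @export
glance.filter_report <- function(x, ...) {
  tibble(
    n_input = x$n_input,
    n_kept = length(x$kept),
    n_removed = nrow(x$removed),
    reduction = x$reduction
  )
}

#' Plot a filter report
#'
#' Bar chart of the missing environment keys versus the number of removed
#' candidates containing each, the visual counterpart of
#' [summarize_missing()].
#'
#' @param object A `filter_report`.
#' @param max_keys Show at most this many keys (most frequent first).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot filter_report
#' @export
autoplot.filter_report <- function(object, max_keys = 20L, ...) {
  tab <- summarize_missing(object) |> slice_head(n = max_keys)
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$n_candidates,
    y = stats::reorder(.data$env_key, .data$n_candidates)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "removed candidates containing the key",
      y = "missing one-sphere environment",
      title = sprintf("Statistical filter: %d of %d candidates removed",
                      nrow(object$removed), object$n_input)
    ) +
    ggplot2::theme_minimal()
}

#' Write a filter report to disk
#'
#' Emits the kept and removed candidates as sorted canonical-SMILES files and
#' the report itself (counts, reduction, per-candidate missing keys, missing
#' key summary) as JSON.
#'
#' @param report A `filter_report`.
#' @param kept_path,removed_path,report_path Output paths (`NULL` skips).
#' @return `report`, invisibly.
#' @export
write_filter_report <- function(report, kept_path = NULL, removed_path = NULL,
                                report_path = NULL) {
  if (!is.null(kept_path)) write_smiles_file(report$kept, kept_path)
  if (!is.null(removed_path)) write_smiles_file(
    if (nrow(report$removed) > 0) report$removed$smiles else character(0),
    removed_path
  )
  if (!is.null(report_path)) {
    jsonlite::write_json(list(
      n_input = report$n_input,
      n_kept = length(report$kept),
      n_removed = nrow(report$removed),
      reduction = report$reduction,
      removed = lapply(seq_len(nrow(report$removed)), function(k) {
        list(smiles = report$removed$smiles[k],
             missing = as.list(report$removed$missing[[k]]))
      }),
      missing_summary = summarize_missing(report)
    ), report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
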