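# The JSON input dialect: molecular formula, per-atom NMR records and
# correlation lists in one document, the package's equivalent of a structure
# generator input file. Validation is strict -- unknown keys are rejected and
# errors carry a JSON-pointer-style path to the offending field. A machine-
# readable schema ships in inst/extdata/nmr_input_schema.json.

input_abort <- function(pointer, msg) {
  abort(paste0("invalid input at ", pointer, ": ", msg),
        class = "nmrcase_input_error")
}

check_keys <- function(x, allowed, required, pointer) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    input_abort(paste0(pointer, "/", unknown[1]), "unknown key")
  }
  miss <- setdiff(required, names(x))
  if (length(miss) > 0) {
    input_abort(pointer, paste0("missing required key '", miss[1], "'"))
  }
}

#' Read an NMR input document
#'
#' Parses and fully validates the JSON input dialect: `formula` (Hill
#' string), `atoms` (id, element, n_h, optional shift_ppm and
#' hybridization), `correlations` (lists `cosy`, `hmbc`, `n15hmbc`,
#' `adequate11` of id pairs) and `options` (generation overrides). All
#' cross-reference checks (dangling ids, proton counts on H-side endpoints)
#' are applied here.
#'
#' @param path Path to a JSON file.
#' @return A list with components `formula` (`mol_formula`), `atoms`
#'   (`atom_specs`), `correlations` (`correlation_set`), `config`
#'   (`generation_config`) and `allow_4bond`.
#' @export
read_nmr_input <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("input file not found: ", path), class = "nmrcase_io_error")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      abort(paste0("not valid JSON: ", path, " (", conditionMessage(e), ")"),
            class = "nmrcase_io_error")
    }
  )
  check_keys(doc, c("formula", "atoms", "correlations", "options"),
             c("formula", "atoms"), "")
  if (!is.character(doc$formula) && !is.null(doc$formula)) {
    input_abort("/formula", "must be a string")
  }
  formula <- parse_formula(doc$formula[[1]])
  if (length(doc$atoms) == 0L) input_abort("/atoms", "must be non-empty")
  atom_rows <- lapply(seq_along(doc$atoms), function(k) {
    a <- doc$atoms[[k]]
    ptr <- paste0("/atoms/", k - 1L)
    check_keys(a, c("id", "element", "n_h", "shift_ppm", "hybridization"),
               c("id", "element", "n_h"), ptr)
    tibble(
      id = as.character(a$id), element = as.character(a$element),
      n_h = if (is.null(a$n_h) || is.na(a$n_h)) NA_integer_ else
        as.integer(a$n_h),
      shift_ppm = if (is.null(a$shift_ppm)) NA_real_ else
        as.numeric(a$shift_ppm),
      hybridization = if (is.null(a$hybridization)) "open" else
        tolower(as.character(a$hybridization))
    )
  })
  atoms <- tryCatch(
    validate_atom_specs(bind_rows(atom_rows)),
    error = function(e) input_abort("/atoms", conditionMessage(e))
  )
  corr <- doc$correlations %||% list()
  check_keys(corr, c("cosy", "hmbc", "n15hmbc", "adequate11"), character(0),
             "/correlations")
  get_pairs <- function(name) {
    pairs <- corr[[name]] %||% list()
    for (k in seq_along(pairs)) {
      if (length(pairs[[k]]) != 2L) {
        input_abort(paste0("/correlations/", name, "/", k - 1L),
                    "must be a pair of atom ids")
      }
    }
    lapply(pairs, function(p) as.character(unlist(p)))
  }
  correlations <- correlation_set(
    cosy = get_pairs("cosy"), hmbc = get_pairs("hmbc"),
    n15hmbc = get_pairs("n15hmbc"), adequate11 = get_pairs("adequate11")
  )
  opts <- doc$options %||% list()
  check_keys(opts, c("open_types", "min_ring_size", "max_results",
                     "forbid_hetero_hetero", "allow_4bond"),
             character(0), "/options")
  config <- generation_config(
    open_types = opts$open_types %||% FALSE,
    min_ring_size = opts$min_ring_size %||% 3L,
    max_results = opts$max_results %||% 1e6,
    forbid_hetero_hetero = opts$forbid_hetero_hetero %||% FALSE
  )
  # cross-reference validation happens in compile_constraints; run it now so
  # a bad document fails at read time with the atom id named
  compile_constraints(correlations, atoms,
                      allow_4bond = isTRUE(opts$allow_4bond))
  list(formula = formula, atoms = atoms, correlations = correlations,
       config = config, allow_4bond = isTRUE(opts$allow_4bond))
}

#' Write an NMR input document
#'
#' Inverse of [read_nmr_input()]: serializes formula, atom specs,
#' correlations and options to the JSON dialect, byte-stable for fixed
#' inputs.
#'
#' @param formula A `mol_formula` or Hill string.
#' @param atoms An `atom_specs` table.
#' @param correlations A `correlation_set`.
#' @param path Output path.
#' @param options Named list of generation options to embed.
#' @return `path`, invisibly.
#' @export
write_nmr_input <- function(formula, atoms, correlations, path,
                            options = list()) {
  if (is.character(formula)) formula <- parse_formula(formula)
  pair_list <- function(tb) {
    lapply(seq_len(nrow(tb)), function(k) c(tb$a[k], tb$b[k]))
  }
  doc <- list(
    formula = format_formula(formula),
    atoms = lapply(seq_len(nrow(atoms)), function(k) {
      rec <- list(id = atoms$id[k], element = atoms$element[k],
                  n_h = atoms$n_h[k])
      if (!is.na(atoms$shift_ppm[k])) rec$shift_ppm <- atoms$shift_ppm[k]
      rec$hybridization <- atoms$hybridization[k]
      rec
    }),
    correlations = list(
      cosy = pair_list(correlations$cosy),
      hmbc = pair_list(correlations$hmbc),
      n15hmbc = pair_list(correlations$n15hmbc),
      adequate11 = pair_list(correlations$adequate11)
    )
  )
  if (length(options) > 0) doc$options <- options
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
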