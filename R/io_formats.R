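# SMILES and SDF (V2000) input/output for constitutions.
#
# SMILES strings are parsed and written through OpenBabel (ChemmineOB), the
# standard open-source format bridge: parsing goes SMILES -> kekulized molfile
# -> constitution, writing goes constitution -> molfile -> canonical SMILES.
# The molfile text codec itself lives here; V2000 carries exactly the fields a
# constitution holds (element, charge, bond order) and implicit hydrogens
# follow the same neutral-valence model.

#' Write constitutions as molfile / SDF V2000 text
#'
#' @param ms A `constitution` or list of them.
#' @param path Optional file path; if `NULL` the SDF text is returned.
#' @param titles Optional character vector of record titles.
#' @return The SDF text (invisibly when written to a file).
#' @export
write_sdf <- function(ms, path = NULL, titles = NULL) {
  if (inherits(ms, "constitution")) ms <- list(ms)
  blocks <- vapply(seq_along(ms), function(k) {
    molfile_text(ms[[k]], title = titles[k] %||% paste0("mol", k))
  }, character(1))
  txt <- paste0(paste0(blocks, collapse = "$$$$\n"), "$$$$\n")
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path)
  invisible(txt)
}

molfile_text <- function(m, title = "mol") {
  a <- m$atoms; b <- m$bonds
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(a), nrow(b))
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s0  %1d  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, a$element, charge_code(a$charge)
  )
  bond_lines <- if (nrow(b) > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, b$order)
  } else character(0)
  chg <- which(a$charge != 0L)
  prop_lines <- if (length(chg) > 0) {
    sprintf("M  CHG%3d%s", length(chg),
            paste0(sprintf("%4d%4d", chg, a$charge[chg]), collapse = ""))
  } else character(0)
  paste0(paste(c(title, "  nmrcase", "", counts, atom_lines, bond_lines,
                 prop_lines, "M  END"), collapse = "\n"), "\n")
}

# legacy molfile charge field: 0 none, 3 = +1, 5 = -1 (M CHG overrides anyway)
charge_code <- function(charge) {
  ifelse(charge == 1L, 3L, ifelse(charge == -1L, 5L, 0L))
}

#' Read constitutions from molfile / SDF V2000 text
#'
#' Implicit hydrogen counts are assigned from the neutral-valence model
#' (`C=4, N=3, O=2, S=2, halogens=1`) minus the bond-order sum and charge
#' magnitude; explicit H atoms in the file are folded into their heavy
#' neighbor's count.
#'
#' @param x A file path or SDF text.
#' @return A list of `constitution` objects.
#' @export
read_sdf <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else {
    strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "$$$$")))
  recs <- Filter(function(r) any(grepl("V2000", r)), recs)
  unname(lapply(recs, parse_molfile_record))
}

parse_molfile_record <- function(lines) {
  hdr <- grep("V2000", lines)[1]
  na <- as.integer(substr(lines[hdr], 1, 3))
  nb <- as.integer(substr(lines[hdr], 4, 6))
  atom_lines <- lines[hdr + seq_len(na)]
  elements <- trimws(substr(atom_lines, 32, 34))
  charges <- integer(na)
  bond_lines <- if (nb > 0) lines[hdr + na + seq_len(nb)] else character(0)
  bi <- as.integer(substr(bond_lines, 1, 3))
  bj <- as.integer(substr(bond_lines, 4, 6))
  bo <- as.integer(substr(bond_lines, 7, 9))
  for (pl in grep("^M  CHG", lines, value = TRUE)) {
    nn <- as.integer(substr(pl, 7, 9))
    for (t in seq_len(nn)) {
      off <- 10 + (t - 1) * 8
      idx <- as.integer(substr(pl, off, off + 3))
      charges[idx] <- as.integer(substr(pl, off + 4, off + 7))
    }
  }
  if (any(bo == 4L)) {
    abort("molfile contains aromatic (order 4) bonds; kekulize it first",
          class = "nmrcase_parse_error")
  }
  # fold explicit hydrogens into heavy-atom H counts
  is_h <- elements == "H"
  bsum <- integer(na)
  n_h_explicit <- integer(na)
  keep_bond <- rep(TRUE, length(bi))
  for (k in seq_along(bi)) {
    if (is_h[bi[k]] || is_h[bj[k]]) {
      heavy <- if (is_h[bi[k]]) bj[k] else bi[k]
      n_h_explicit[heavy] <- n_h_explicit[heavy] + 1L
      keep_bond[k] <- FALSE
    } else {
      bsum[bi[k]] <- bsum[bi[k]] + bo[k]
      bsum[bj[k]] <- bsum[bj[k]] + bo[k]
    }
  }
  keep <- which(!is_h)
  remap <- match(seq_len(na), keep)
  n_h <- valence_of(elements[keep]) - abs(charges[keep]) - bsum[keep]
  n_h <- pmax(n_h, 0L)
  kb <- which(keep_bond)
  constitution(
    atoms = tibble(element = elements[keep], charge = charges[keep],
                   n_h = as.integer(n_h)),
    bonds = tibble(i = remap[bi[kb]], j = remap[bj[kb]], order = bo[kb])
  )
}

#' Parse SMILES strings into constitutions
#'
#' Aromatic SMILES are kekulized by OpenBabel during conversion, so each
#' aromatic system arrives as one Kekule form; canonical keys and environment
#' keys re-merge the forms downstream.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A list of `constitution` objects (one per input string).
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  sdf <- ChemmineOB::convertFormat(
    "SMI", "SDF", paste0(paste(smiles, collapse = "\n"), "\n")
  )
  out <- read_sdf(sdf)
  if (length(out) != length(smiles)) {
    abort(paste0("OpenBabel parsed ", length(out), " of ", length(smiles),
                 " SMILES record(s)"), class = "nmrcase_parse_error")
  }
  out
}

#' Write constitutions as canonical SMILES
#'
#' @param ms A `constitution` or list of them.
#' @return Character vector of OpenBabel canonical SMILES.
#' @export
as_smiles <- function(ms) {
  if (inherits(ms, "constitution")) ms <- list(ms)
  if (length(ms) == 0L) return(character(0))
  out <- ChemmineOB::convertFormat("SDF", "CAN", write_sdf(ms))
  smi <- strsplit(out, "\n", fixed = TRUE)[[1]]
  vapply(strsplit(smi, "\t", fixed = TRUE), `[[`, character(1), 1)
}

#' Read a SMILES file (one molecule per line)
#'
#' Unparseable lines are skipped with a warning that reports their count.
#'
#' @param path File path; lines may carry a whitespace-separated title.
#' @return A list of `constitution` objects; skipped line count in attribute
#'   `n_skipped`.
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("SMILES file not found: ", path), class = "nmrcase_io_error")
  }
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  smi <- vapply(strsplit(lines, "[ \t]+"), `[[`, character(1), 1)
  out <- vector("list", length(smi))
  ok <- logical(length(smi))
  for (k in seq_along(smi)) {
    res <- tryCatch(parse_smiles(smi[k])[[1]], error = function(e) NULL)
    if (!is.null(res)) { out[[k]] <- res; ok[k] <- TRUE }
  }
  if (any(!ok)) {
    warn(paste0("skipped ", sum(!ok), " unparseable SMILES line(s)"))
  }
  structure(out[ok], n_skipped = sum(!ok))
}

#' Write canonical SMILES to a file, sorted lexically
#'
#' @param ms List of `constitution` objects (or character SMILES).
#' @param path Output path.
#' @return The sorted SMILES, invisibly.
#' @export
write_smiles_file <- function(ms, path) {
  smi <- if (is.character(ms)) ms else as_smiles(ms)
  smi <- sort(smi, method = "radix")
  writeLines(smi, path)
  invisible(smi)
}
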