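#' @keywords internal
#' @importFrom rlang .data
#' @importFrom Rcpp evalCpp
#' @useDynLib adaptmol, .registration = TRUE
"_PACKAGE"

# Cheminformatics backend: a bundled RDKit batch script invoked through the
# `python` interpreter on the PATH. All calls are batched (one subprocess per
# vector of molecules) and deterministic.

chem_python <- function() {
  p <- Sys.getenv("ADAPTMOL_PYTHON", unset = Sys.which("python"))
  if (!nzchar(p)) {
    stop("No `python` interpreter found on the PATH; the cheminformatics ",
         "backend requires Python with RDKit.", call. = FALSE)
  }
  p
}

chem_script <- function() {
  s <- system.file("python", "chem_backend.py", package = "adaptmol")
  if (!nzchar(s)) stop("chem_backend.py not found in the installed package")
  s
}

chem_call <- function(command, smiles, args = character()) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character())
  bad <- grepl("[\n\t]", smiles)
  if (any(bad)) stop("SMILES strings must not contain tabs or newlines")
  out <- suppressWarnings(system2(
    chem_python(), c(chem_script(), command, args),
    input = smiles, stdout = TRUE, stderr = FALSE
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("cheminformatics backend failed (command '", command, "', status ",
         status, ")")
  }
  if (length(out) != length(smiles)) {
    stop("cheminformatics backend returned ", length(out), " lines for ",
         length(smiles), " inputs")
  }
  out
}

#' Canonicalize SMILES and flag validity
#'
#' Parses each string with the cheminformatics toolkit and returns the
#' toolkit's canonical SMILES. Validity means the string parses as a molecule
#' (syntactic and valence checks); the empty string parses as the zero-atom
#' molecule and is therefore valid with canonical form `""`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A tibble with columns `smiles`, `valid` (logical) and `canonical`
#'   (`NA` where invalid).
#' @export
#' @examples
#' \dontrun{
#' chem_canonicalize(c("OCC", "C1=CC=CC=C1", "not_a_molecule"))
#' }
chem_canonicalize <- function(smiles) {
  out <- chem_call("canon", smiles)
  parts <- strsplit(out, "\t", fixed = TRUE)
  valid <- vapply(parts, function(p) p[[1]] == "1", logical(1))
  canon <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", character(1))
  canon[!valid] <- NA_character_
  tibble::tibble(smiles = smiles, valid = valid, canonical = canon)
}

# props: valid, MW, TPSA, LogP, HBD, HBA, QED, SA per molecule
chem_properties <- function(smiles) {
  out <- chem_call("props", smiles)
  parts <- strsplit(out, "\t", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, function(p) c(p, rep(NA, 8 - length(p)))))
  valid <- m[, 1] == "1"
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  tibble::tibble(
    smiles = smiles, valid = valid,
    mw = num(2), tpsa = num(3), logp = num(4),
    hbd = num(5), hba = num(6), qed = num(7), sa = num(8)
  )
}

# 2533-column numeric feature matrix (FCFP6 2048 + MACCS 166 + 319 descriptors)
chem_feature_matrix <- function(smiles) {
  manifest <- system.file("extdata", "qsar_descriptors.txt", package = "adaptmol")
  out <- chem_call("features", smiles, args = manifest)
  rows <- strsplit(out, "\t", fixed = TRUE)
  ok <- vapply(rows, function(r) r[[1]] == "1", logical(1))
  if (!all(ok)) {
    stop("featurization failed for molecule(s): ",
         paste(utils::head(smiles[!ok], 5), collapse = ", "))
  }
  mat <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(2533)))
  desc_names <- readLines(manifest)
  colnames(mat) <- c(paste0("FCFP6_", seq_len(2048)),
                     paste0("MACCS_", seq_len(166)),
                     desc_names)
  mat
}

# kekulized molecule graphs (atoms + bonds) for the SELFIES encoder
chem_graphs <- function(smiles) {
  out <- chem_call("graph", smiles)
  lapply(out, function(line) jsonlite::fromJSON(line, simplifyMatrix = TRUE))
}
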