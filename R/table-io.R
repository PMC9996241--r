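PHOSPHO_RESIDUES <- c("S", "T", "Y")
MUTATION_CLASSES <- c("missense", "nonsense", "frameshift_indel",
                      "inframe_indel", "splice_site", "stop_loss", "silent")
# classes contributing to the binary mutation matrix (silent and splice_site
# records carry no confident protein-level consequence usable here)
QUALIFYING_CLASSES <- c("missense", "nonsense", "frameshift_indel",
                        "inframe_indel", "stop_loss")
LOF_CLASSES <- c("frameshift_indel", "nonsense", "splice_site", "stop_loss")
PRIOR_SOURCES <- c("database", "textmining", "invivo", "invitro")

#' Canonical phosphosite key
#'
#' Sites are identified by host protein, 1-based position and phospho-residue
#' (S, T or Y), rendered as e.g. `"AKT1_S473"`.
#'
#' @param protein,position,residue site coordinates (vectorised).
#' @return character vector of keys.
#' @export
site_key <- function(protein, position, residue) {
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L))
    stop("phosphosite positions must be integers >= 1")
  residue <- as.character(residue)
  bad <- setdiff(unique(residue), PHOSPHO_RESIDUES)
  if (length(bad))
    stop("phosphosite residue outside {S,T,Y}: ", paste(bad, collapse = ", "))
  paste0(protein, "_", residue, position)
}

# inverse of site_key(); returns data.frame(protein, position, residue)
parse_site_key <- function(keys) {
  m <- regmatches(keys, regexec("^(.*)_([STY])([0-9]+)$", keys))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed site key: ", keys[bad][1])
  data.frame(protein = vapply(m, `[`, "", 2L),
             position = as.integer(vapply(m, `[`, "", 4L)),
             residue = vapply(m, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Read kinase-substrate and TF-regulon priors
#'
#' The kinase file is tab-separated with columns `kinase`, `protein`,
#' `position`, `residue`, `source`; the regulon file has `tf`, `target`,
#' `mode`, `confidence`. Regulation modes accept numeric `+1`/`-1` or the
#' `A` (activating) / `I` (inhibiting) aliases.
#'
#' @param kinase_file path to the kinase-substrate table, or `NULL`.
#' @param regulon_file path to the TF-regulon table, or `NULL`.
#' @return list with data.frame components `kinase_targets` (with a `site`
#'   key column) and `regulons` (mode coerced to -1/+1).
#' @export
read_prior <- function(kinase_file = NULL, regulon_file = NULL) {
  out <- list(kinase_targets = NULL, regulons = NULL)
  if (!is.null(kinase_file)) {
    kt <- read.delim(kinase_file, header = TRUE, sep = "\t",
                     colClasses = "character", quote = "")
    need <- c("kinase", "protein", "position", "residue", "source")
    if (!all(need %in% names(kt)))
      stop("kinase prior must have columns: ", paste(need, collapse = ", "))
    kt$position <- as.integer(kt$position)
    kt$site <- site_key(kt$protein, kt$position, kt$residue)
    bad <- setdiff(unique(kt$source), PRIOR_SOURCES)
    if (length(bad)) stop("unknown prior source: ", paste(bad, collapse = ", "))
    out$kinase_targets <- kt
  }
  if (!is.null(regulon_file)) {
    rg <- read.delim(regulon_file, header = TRUE, sep = "\t",
                     colClasses = "character", quote = "")
    need <- c("tf", "target", "mode", "confidence")
    if (!all(need %in% names(rg)))
      stop("regulon prior must have columns: ", paste(need, collapse = ", "))
    rg$mode <- mode_from_alias(rg$mode)
    bad <- setdiff(unique(rg$confidence), c("A", "B", "C"))
    if (length(bad)) stop("regulon confidence outside {A,B,C}: ",
                          paste(bad, collapse = ", "))
    out$regulons <- rg
  }
  out
}

mode_from_alias <- function(mode) {
  map <- c("A" = 1, "I" = -1, "1" = 1, "+1" = 1, "-1" = -1)
  out <- unname(map[as.character(mode)])
  if (any(is.na(out)))
    stop("regulation mode outside {-1,+1,A,I}: ",
         paste(unique(mode[is.na(out)]), collapse = ", "))
  out
}

#' Write priors to tab-separated files
#' @param prior a prior list as returned by [read_prior()].
#' @param kinase_file,regulon_file output paths (skipped when `NULL`).
#' @return invisibly, the prior.
#' @export
write_prior <- function(prior, kinase_file = NULL, regulon_file = NULL) {
  if (!is.null(kinase_file) && !is.null(prior$kinase_targets)) {
    kt <- prior$kinase_targets
    write_tsv(kt[, c("kinase", "protein", "position", "residue", "source")],
              kinase_file)
  }
  if (!is.null(regulon_file) && !is.null(prior$regulons))
    write_tsv(prior$regulons[, c("tf", "target", "mode", "confidence")],
              regulon_file)
  invisible(prior)
}

#' Read a somatic mutation table
#'
#' Tab-separated with columns `sample_id`, `gene`, `mclass`, `position`,
#' `ref_residue`, `alt_residue`. Splice-site records may lack position and
#' residues; every other class must carry them.
#'
#' @param path file path.
#' @return data.frame of mutation records.
#' @export
read_mutations <- function(path) {
  mt <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   na.strings = "NA", quote = "")
  need <- c("sample_id", "gene", "mclass", "position", "ref_residue",
            "alt_residue")
  if (!all(need %in% names(mt)))
    stop("mutation table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(mt$mclass), MUTATION_CLASSES)
  if (length(bad)) stop("unknown mutation class: ", paste(bad, collapse = ", "))
  mt$position <- suppressWarnings(as.integer(mt$position))
  validate_mutations(mt)
  mt
}

validate_mutations <- function(mt) {
  nonsplice <- mt$mclass != "splice_site"
  miss <- nonsplice & (is.na(mt$position) | is.na(mt$ref_residue) |
                         is.na(mt$alt_residue))
  if (any(miss))
    stop("non-splice mutation records must carry position and residues (",
         sum(miss), " offending records, first gene ", mt$gene[miss][1], ")")
  if (any(nonsplice & !is.na(mt$position) & mt$position < 1L))
    stop("mutation positions must be >= 1")
  invisible(mt)
}

#' Write a mutation table
#' @param mutations data.frame as from [read_mutations()].
#' @param path output path.
#' @export
write_mutations <- function(mutations, path) {
  write_tsv(mutations[, c("sample_id", "gene", "mclass", "position",
                          "ref_residue", "alt_residue")], path)
}

#' Read a confidence-scored protein-pair edge list
#'
#' Tab-separated with columns `protein_a`, `protein_b`, `combined_score`.
#' Scores must lie in \[150, 999\]. Pairs are undirected and stored
#' canonically with the lexicographically smaller id first.
#'
#' @param path file path.
#' @return data.frame with canonical pairs and integer scores.
#' @export
read_edges <- function(path) {
  ed <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   quote = "")
  need <- c("protein_a", "protein_b", "combined_score")
  if (!all(need %in% names(ed)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  ed$combined_score <- as.integer(ed$combined_score)
  if (any(is.na(ed$combined_score)) ||
      any(ed$combined_score < 150L | ed$combined_score > 999L))
    stop("combined_score must be an integer in [150, 999]")
  canonical_edges(ed)
}

canonical_edges <- function(ed) {
  a <- pmin(ed$protein_a, ed$protein_b)
  b <- pmax(ed$protein_a, ed$protein_b)
  out <- data.frame(protein_a = a, protein_b = b,
                    combined_score = ed$combined_score,
                    stringsAsFactors = FALSE)
  out[!duplicated(paste(out$protein_a, out$protein_b)), , drop = FALSE]
}

#' Write an edge list
#' @param edges data.frame as from [read_edges()].
#' @param path output path.
#' @export
write_edges <- function(edges, path) {
  write_tsv(edges[, c("protein_a", "protein_b", "combined_score")], path)
}

#' Read protein sequences from FASTA
#'
#' Headers are truncated at the first whitespace to form protein ids; a
#' duplicated id is an error.
#'
#' @param path FASTA file path.
#' @return named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA header: ", paste(unique(dup), collapse = ", "))
  setNames(as.character(seqs), ids)
}

#' Write protein sequences to FASTA
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Read a clinical/survival table
#'
#' Tab-separated, one row per sample, with at least `sample_id` and `study`;
#' recognised optional columns are `tissue`, `sample_type`, `age`, `gender`,
#' `bmi`, `os_time_days`, `os_event` and `subtype`. An `os_event` without an
#' `os_time_days` is an error, as is a negative survival time.
#'
#' @param path file path.
#' @return data.frame with numeric clinical columns coerced.
#' @export
read_clinical <- function(path) {
  cl <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   na.strings = "NA", quote = "")
  if (!all(c("sample_id", "study") %in% names(cl)))
    stop("clinical table must have sample_id and study columns")
  for (col in intersect(c("age", "bmi", "os_time_days"), names(cl)))
    cl[[col]] <- as.numeric(cl[[col]])
  if ("os_event" %in% names(cl)) cl$os_event <- as.integer(cl$os_event)
  validate_clinical(cl)
  cl
}

validate_clinical <- function(cl) {
  if ("os_event" %in% names(cl)) {
    if (!all(cl$os_event[!is.na(cl$os_event)] %in% 0:1))
      stop("os_event must be 0/1")
    if ("os_time_days" %in% names(cl)) {
      if (any(!is.na(cl$os_event) & is.na(cl$os_time_days)))
        stop("os_event recorded without os_time_days")
      if (any(cl$os_time_days[!is.na(cl$os_time_days)] < 0))
        stop("os_time_days must be >= 0")
    } else if (any(!is.na(cl$os_event))) {
      stop("os_event recorded without os_time_days")
    }
  }
  invisible(cl)
}

#' Write a clinical table
#' @param clinical data.frame as from [read_clinical()].
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) write_tsv(clinical, path)

#' Read a gold-standard table of kinase-condition regulation events
#' @param path tab-separated file with columns `kinase`, `condition_id` and
#'   optionally `direction`; (kinase, condition) pairs must be unique.
#' @return data.frame.
#' @export
read_gold_standard <- function(path) {
  gs <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   quote = "")
  if (!all(c("kinase", "condition_id") %in% names(gs)))
    stop("gold standard must have kinase and condition_id columns")
  key <- paste(gs$kinase, gs$condition_id)
  if (anyDuplicated(key)) stop("duplicated (kinase, condition) pair")
  gs
}
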