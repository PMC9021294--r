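#' Reference set for small-RNA mapping
#'
#' Container holding the sequence space reads are mapped against: mature
#' tRNAs (with the post-transcriptionally added 3' CCA), pre-tRNA 3'
#' trailers, mature miRNAs, spike-in controls, and a table of annotated
#' modification sites. It is the coordinate frame for everything downstream.
#'
#' Sequences are stored in the DNA alphabet (U -> T), matching sequencing
#' output. Names must be unique across all categories.
#'
#' @param trnas data.frame with columns `name`, `anticodon`, `compartment`
#'   (`"nuclear"` or `"mitochondrial"`), `sequence`. Sequences must end in
#'   `"CCA"` and be 60-100 nt.
#' @param trailers data.frame with columns `name`, `parent` (a tRNA name),
#'   `sequence`.
#' @param mirnas data.frame with columns `name`, `sequence`.
#' @param spikeins data.frame with columns `name`, `sequence`, `is_qc`
#'   (logical; `TRUE` for quantification spike-ins used as normalization
#'   denominator).
#' @param mod_sites data.frame with columns `reference`, `position` (1-based
#'   on that reference), `modification` (e.g. `"m1A"`), `writer` (enzyme tag
#'   or `NA`).
#' @return an object of class `ReferenceSet`.
#' @export
reference_set <- function(trnas, trailers = NULL, mirnas = NULL,
                          spikeins = NULL, mod_sites = NULL) {
  empty <- function(...) {
    cols <- c(...)
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                  stringsAsFactors = FALSE)
  }
  trailers <- trailers %||% empty("name", "parent", "sequence")
  mirnas   <- mirnas   %||% empty("name", "sequence")
  spikeins <- spikeins %||% cbind(empty("name", "sequence"),
                                  is_qc = logical(0))
  mod_sites <- mod_sites %||% data.frame(reference = character(0),
                                         position = integer(0),
                                         modification = character(0),
                                         writer = character(0),
                                         stringsAsFactors = FALSE)

  trnas$length <- nchar(trnas$sequence)
  ref <- structure(list(trnas = trnas, trailers = trailers, mirnas = mirnas,
                        spikeins = spikeins, mod_sites = mod_sites),
                   class = "ReferenceSet")

  seqs <- c(stats::setNames(trnas$sequence, trnas$name),
            stats::setNames(trailers$sequence, trailers$name),
            stats::setNames(mirnas$sequence, mirnas$name),
            stats::setNames(spikeins$sequence, spikeins$name))
  category <- c(rep("tRNA", nrow(trnas)), rep("trailer", nrow(trailers)),
                rep("miR", nrow(mirnas)), rep("spikeIn", nrow(spikeins)))
  names(category) <- names(seqs)
  ref$seqs <- seqs
  ref$category <- category
  validate_reference_set(ref)
  ref
}

#' @noRd
validate_reference_set <- function(ref) {
  nm <- names(ref$seqs)
  if (anyDuplicated(nm))
    stop("reference names not unique: ", nm[duplicated(nm)][1L])
  if (any(grepl("[^ACGT]", ref$seqs)))
    stop("reference sequences must use the A/C/G/T alphabet")
  tr <- ref$trnas
  if (nrow(tr)) {
    if (any(substr(tr$sequence, tr$length - 2L, tr$length) != "CCA"))
      stop("mature tRNA sequences must end in CCA")
    if (any(tr$length < 60L | tr$length > 100L))
      stop("mature tRNA lengths must be within 60..100 nt")
    if (any(!tr$compartment %in% c("nuclear", "mitochondrial")))
      stop("tRNA compartment must be 'nuclear' or 'mitochondrial'")
  }
  if (nrow(ref$trailers)) {
    if (any(nchar(ref$trailers$sequence) == 0L)) stop("empty trailer sequence")
    miss <- setdiff(ref$trailers$parent, tr$name)
    if (length(miss)) stop("trailer parent not in tRNA set: ", miss[1L])
  }
  ms <- ref$mod_sites
  if (nrow(ms)) {
    miss <- setdiff(ms$reference, nm)
    if (length(miss)) stop("modification site on unknown reference: ", miss[1L])
    len <- nchar(ref$seqs[ms$reference])
    if (any(ms$position < 1L | ms$position > len))
      stop("modification position outside its reference")
    base <- substr(ref$seqs[ms$reference], ms$position, ms$position)
    if (any(ms$modification == "m1A" & base != "A"))
      stop("m1A annotated at a non-A position")
  }
  # spike-ins must be distinguishable from the biological reference space
  sp <- ref$spikeins
  if (nrow(sp)) {
    others <- ref$seqs[ref$category != "spikeIn"]
    for (s in sp$sequence)
      if (any(vapply(others, function(o) grepl(s, o, fixed = TRUE), TRUE)))
        stop("spike-in sequence occurs inside another reference")
  }
  invisible(ref)
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat("ReferenceSet:", nrow(x$trnas), "tRNAs,", nrow(x$trailers), "trailers,",
      nrow(x$mirnas), "miRNAs,", nrow(x$spikeins), "spike-ins,",
      nrow(x$mod_sites), "modification sites\n")
  invisible(x)
}

#' @rdname reference_set
#' @param ref a `ReferenceSet`.
#' @param name reference name.
#' @export
ref_sequence <- function(ref, name) {
  s <- ref$seqs[name]
  if (anyNA(s)) stop("unknown reference: ", name[is.na(s)][1L])
  unname(s)
}

#' @rdname reference_set
#' @export
ref_length <- function(ref, name) nchar(ref_sequence(ref, name))

#' Write / read a reference set as multi-FASTA files plus a TSV site table
#'
#' One FASTA per category (`trnas.fa`, `trailers.fa`, `mirnas.fa`,
#' `spikeins.fa`) with metadata carried in the headers, and
#' `mod_sites.tsv` with columns reference, position, modification, writer.
#'
#' @param ref a `ReferenceSet`.
#' @param dir directory to write into (created if needed).
#' @return `write_reference_set()` returns `dir` invisibly;
#'   `read_reference_set()` returns a `ReferenceSet`.
#' @export
write_reference_set <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(seqs, headers, file) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- headers
    Biostrings::writeXStringSet(x, file.path(dir, file))
  }
  tr <- ref$trnas
  wr(tr$sequence,
     sprintf("%s anticodon=%s compartment=%s", tr$name, tr$anticodon,
             tr$compartment), "trnas.fa")
  wr(ref$trailers$sequence,
     sprintf("%s parent=%s", ref$trailers$name, ref$trailers$parent),
     "trailers.fa")
  wr(ref$mirnas$sequence, ref$mirnas$name, "mirnas.fa")
  wr(ref$spikeins$sequence,
     sprintf("%s is_qc=%s", ref$spikeins$name,
             tolower(ref$spikeins$is_qc)), "spikeins.fa")
  utils::write.table(ref$mod_sites, file.path(dir, "mod_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_reference_set
#' @export
read_reference_set <- function(dir) {
  rd <- function(file) {
    path <- file.path(dir, file)
    x <- Biostrings::readDNAStringSet(path)
    data.frame(header = names(x), sequence = as.character(x),
               stringsAsFactors = FALSE)
  }
  field <- function(h, key) sub(sprintf(".*%s=([^ ]+).*", key), "\\1", h)
  first <- function(h) sub(" .*", "", h)

  tr <- rd("trnas.fa")
  trnas <- data.frame(name = first(tr$header),
                      anticodon = field(tr$header, "anticodon"),
                      compartment = field(tr$header, "compartment"),
                      sequence = tr$sequence, stringsAsFactors = FALSE)
  tl <- rd("trailers.fa")
  trailers <- data.frame(name = first(tl$header),
                         parent = field(tl$header, "parent"),
                         sequence = tl$sequence, stringsAsFactors = FALSE)
  mi <- rd("mirnas.fa")
  mirnas <- data.frame(name = first(mi$header), sequence = mi$sequence,
                       stringsAsFactors = FALSE)
  sp <- rd("spikeins.fa")
  spikeins <- data.frame(name = first(sp$header), sequence = sp$sequence,
                         is_qc = field(sp$header, "is_qc") == "true",
                         stringsAsFactors = FALSE)
  ms <- utils::read.table(file.path(dir, "mod_sites.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  reference_set(trnas, trailers, mirnas, spikeins, ms)
}
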