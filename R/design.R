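#' @useDynLib sgescore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats loess loess.control median optim pnorm dnorm predict
#'   quantile rbinom rgamma rmultinom rnorm runif sd setNames complete.cases
#'   cor qnorm fitted
#' @importFrom graphics abline segments hist lines
#' @importFrom utils read.delim write.table head modifyList
NULL

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "*")

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

#' Describe an SGE amplicon design
#'
#' An amplicon design ties together everything the pipeline needs to interpret
#' reads from one saturation-genome-editing experiment: the reference amplicon
#' sequence, where the exon(s) sit inside it, how amplicon positions map to
#' HGVS c. coordinates, where Cas9 cuts, the fixed synonymous PAM/HDR-marker
#' edit(s), and the saturated target region.
#'
#' Amplicon positions are 0-based half-open internally; HGVS c. coordinates at
#' the interface are 1-based with `+`/`-` intron offsets.
#'
#' @param amplicon_id character identifier.
#' @param reference_seq reference amplicon sequence (character, ACGT).
#' @param exon_intervals matrix or list of `(start, end)` exon intervals in
#'   amplicon coordinates, 0-based half-open, sorted, non-overlapping.
#' @param cdna_offset integer: the first exonic base of the amplicon has
#'   HGVS coordinate `c.(cdna_offset + 1)`.
#' @param cut_sites integer vector of blunt-cut positions (the cut falls
#'   between `pos - 1` and `pos`).
#' @param marker_edits data.frame with columns `pos`, `ref`, `alt`: the fixed
#'   synonymous HDR-marker substitutions that gate variant counting.
#' @param target_region `(start, end)` of the saturated region, amplicon
#'   coordinates, half-open.
#' @param cds_frame_offset optional integer phase of the first exonic base;
#'   must equal `cdna_offset %% 3` when supplied.
#' @return An object of class `amplicon_design`.
#' @export
amplicon_design <- function(amplicon_id, reference_seq, exon_intervals,
                            cdna_offset, cut_sites, marker_edits,
                            target_region, cds_frame_offset = NULL) {
  reference_seq <- toupper(as.character(reference_seq))
  if (!grepl("^[ACGT]+$", reference_seq))
    stop("reference_seq must contain only A, C, G, T")
  n <- nchar(reference_seq)
  if (is.list(exon_intervals))
    exon_intervals <- do.call(rbind, lapply(exon_intervals, as.integer))
  exon_intervals <- matrix(as.integer(exon_intervals), ncol = 2)
  colnames(exon_intervals) <- c("start", "end")
  if (any(exon_intervals[, 1] >= exon_intervals[, 2]) ||
      any(exon_intervals < 0) || any(exon_intervals > n))
    stop("invalid exon intervals")
  if (nrow(exon_intervals) > 1) {
    o <- order(exon_intervals[, 1])
    exon_intervals <- exon_intervals[o, , drop = FALSE]
    if (any(exon_intervals[-1, 1] < exon_intervals[-nrow(exon_intervals), 2]))
      stop("exon intervals overlap")
  }
  cut_sites <- as.integer(cut_sites)
  if (any(cut_sites < 0 | cut_sites > n)) stop("cut site outside amplicon")
  marker_edits <- as.data.frame(marker_edits)
  stopifnot(all(c("pos", "ref", "alt") %in% names(marker_edits)))
  marker_edits$pos <- as.integer(marker_edits$pos)
  if (any(marker_edits$pos < 0 | marker_edits$pos >= n))
    stop("marker edit outside amplicon")
  ref_at <- substring(reference_seq, marker_edits$pos + 1, marker_edits$pos + 1)
  if (any(ref_at != toupper(marker_edits$ref)))
    stop("marker ref base does not match reference")
  target_region <- as.integer(target_region)
  if (length(target_region) != 2 || target_region[1] >= target_region[2] ||
      target_region[1] < 0 || target_region[2] > n)
    stop("invalid target region")
  if (is.null(cds_frame_offset)) cds_frame_offset <- cdna_offset %% 3L
  if (cds_frame_offset != cdna_offset %% 3L)
    stop("cds_frame_offset inconsistent with cdna_offset")
  d <- structure(list(amplicon_id = amplicon_id,
                      reference_seq = reference_seq,
                      exon_intervals = exon_intervals,
                      cdna_offset = as.integer(cdna_offset),
                      cds_frame_offset = as.integer(cds_frame_offset),
                      cut_sites = cut_sites,
                      marker_edits = marker_edits,
                      target_region = target_region),
                 class = "amplicon_design")
  # the marker must be synonymous under the declared frame
  for (k in seq_len(nrow(marker_edits))) {
    if (is_exonic(d, marker_edits$pos[k])) {
      cons <- annotate_consequence(d, variant_key(
        d, data.frame(pos = marker_edits$pos[k],
                      ref = marker_edits$ref[k],
                      alt = marker_edits$alt[k]), check_marker = FALSE))
      if (cons$kind != "synonymous")
        stop("marker edit at position ", marker_edits$pos[k],
             " is not synonymous")
    }
  }
  d
}

#' @export
print.amplicon_design <- function(x, ...) {
  cat("Amplicon design '", x$amplicon_id, "': ",
      nchar(x$reference_seq), " bp, ", nrow(x$exon_intervals),
      " exon(s), cut at ", paste(x$cut_sites, collapse = ", "),
      ", target region [", x$target_region[1], ", ", x$target_region[2],
      "), first exonic base c.", x$cdna_offset + 1L, "\n", sep = "")
  invisible(x)
}

exonic_positions <- function(design) {
  unlist(apply(design$exon_intervals, 1,
               function(iv) seq.int(iv[1], iv[2] - 1L)))
}

is_exonic <- function(design, pos) {
  any(pos >= design$exon_intervals[, 1] & pos < design$exon_intervals[, 2])
}

#' Map an amplicon position to an HGVS c. coordinate
#'
#' Exonic positions map to a plain c. coordinate (`offset = 0`); intronic
#' positions map to the nearest exon-boundary c. coordinate plus a signed
#' intron offset (`c.7007+7`, `c.6938-12`), anchoring to the closer exon
#' (ties anchor downstream of the preceding exon, i.e. a `+` offset).
#'
#' @param design an [amplicon_design()].
#' @param amplicon_pos 0-based amplicon position.
#' @return list with `cdna` (integer) and `offset` (integer, 0 for exonic).
#' @export
map_position <- function(design, amplicon_pos) {
  n <- nchar(design$reference_seq)
  if (amplicon_pos < 0 || amplicon_pos >= n)
    stop("position ", amplicon_pos, " outside amplicon [0, ", n, ")")
  ex <- exonic_positions(design)
  if (amplicon_pos %in% ex) {
    return(list(cdna = design$cdna_offset + match(amplicon_pos, ex),
                offset = 0L))
  }
  iv <- design$exon_intervals
  prev_end <- suppressWarnings(max(iv[iv[, 2] <= amplicon_pos, 2]))  # one past last exonic base
  next_start <- suppressWarnings(min(iv[iv[, 1] > amplicon_pos, 1]))
  d_prev <- if (is.finite(prev_end)) amplicon_pos - (prev_end - 1L) else Inf
  d_next <- if (is.finite(next_start)) next_start - amplicon_pos else Inf
  if (d_prev <= d_next) {
    anchor <- design$cdna_offset + match(prev_end - 1L, ex)
    list(cdna = anchor, offset = as.integer(d_prev))
  } else {
    anchor <- design$cdna_offset + match(next_start, ex)
    list(cdna = anchor, offset = -as.integer(d_next))
  }
}

#' Inverse of [map_position()]
#' @param design an [amplicon_design()].
#' @param cdna anchor c. coordinate.
#' @param offset signed intron offset (0 for exonic).
#' @return 0-based amplicon position.
#' @export
cdna_to_pos <- function(design, cdna, offset = 0L) {
  ex <- exonic_positions(design)
  idx <- cdna - design$cdna_offset
  if (idx < 1 || idx > length(ex))
    stop("c.", cdna, " not covered by this amplicon")
  pos <- ex[idx] + as.integer(offset)
  if (pos < 0 || pos >= nchar(design$reference_seq))
    stop("c.", cdna, format_offset(offset), " falls outside the amplicon")
  pos
}

format_offset <- function(offset) {
  if (offset == 0) "" else if (offset > 0) paste0("+", offset)
  else as.character(offset)
}

#' Format an amplicon position as an HGVS c. label (without ref/alt)
#' @inheritParams map_position
#' @return character like `"171"`, `"6938-12"`, `"7007+7"`.
#' @export
cdna_label <- function(design, amplicon_pos) {
  m <- map_position(design, amplicon_pos)
  paste0(m$cdna, format_offset(m$offset))
}

parse_cdna_label <- function(label) {
  label <- sub("^c\\.", "", label)
  m <- regmatches(label, regexec("^(\\d+)([+-]\\d+)?$", label))[[1]]
  if (length(m) == 0) stop("cannot parse c. label: ", label)
  list(cdna = as.integer(m[2]),
       offset = if (m[3] == "") 0L else as.integer(m[3]))
}

resolve_position <- function(design, where) {
  if (is.character(where)) {
    p <- parse_cdna_label(where)
    cdna_to_pos(design, p$cdna, p$offset)
  } else as.integer(where)
}

#' Construct a variant key
#'
#' A variant key identifies a (possibly multi-base) substitution allele by its
#' sorted edits and canonical HGVS c. label. The fixed HDR-marker edits are
#' design metadata and are never part of the key.
#'
#' @param design an [amplicon_design()].
#' @param edits data.frame with columns `pos` (0-based amplicon), `ref`, `alt`.
#' @param check_marker error if an edit coincides with a marker position.
#' @return object of class `variant_key` with `hgvs_c`, `hgvs_p`,
#'   `consequence` fields.
#' @export
variant_key <- function(design, edits, check_marker = TRUE) {
  edits <- as.data.frame(edits)
  stopifnot(nrow(edits) > 0, all(c("pos", "ref", "alt") %in% names(edits)))
  edits$pos <- vapply(edits$pos, resolve_position, integer(1), design = design)
  edits$ref <- toupper(edits$ref); edits$alt <- toupper(edits$alt)
  edits <- edits[order(edits$pos), c("pos", "ref", "alt")]
  if (anyDuplicated(edits$pos)) stop("duplicate edit positions")
  ref_at <- substring(design$reference_seq, edits$pos + 1, edits$pos + 1)
  if (any(ref_at != edits$ref))
    stop("edit ref base(s) do not match the reference: position(s) ",
         paste(edits$pos[ref_at != edits$ref], collapse = ", "))
  if (any(edits$ref == edits$alt)) stop("edit with ref == alt")
  if (check_marker && any(edits$pos %in% design$marker_edits$pos))
    stop("edit coincides with an HDR-marker position")
  key <- structure(list(amplicon_id = design$amplicon_id, edits = edits,
                        hgvs_c = NA_character_, hgvs_p = "",
                        consequence = NULL),
                   class = "variant_key")
  key$hgvs_c <- hgvs_c_of(design, edits)
  cons <- annotate_consequence(design, key)
  key$consequence <- cons
  key$hgvs_p <- cons$hgvs_p
  key
}

hgvs_c_of <- function(design, edits) {
  runs <- split(seq_len(nrow(edits)),
                cumsum(c(1, diff(edits$pos) != 1)))
  lab <- vapply(runs, function(idx) {
    e <- edits[idx, , drop = FALSE]
    if (nrow(e) == 1) {
      paste0(cdna_label(design, e$pos), e$ref, ">", e$alt)
    } else {
      paste0(cdna_label(design, e$pos[1]), "_",
             cdna_label(design, e$pos[nrow(e)]),
             paste(e$ref, collapse = ""), ">", paste(e$alt, collapse = ""))
    }
  }, character(1))
  paste0("c.", paste(lab, collapse = ";"))
}

#' @export
print.variant_key <- function(x, ...) {
  cat(x$hgvs_c, if (nzchar(x$hgvs_p)) paste0(" (", x$hgvs_p, ")"), " [",
      x$consequence$kind, "]\n", sep = "")
  invisible(x)
}

#' Annotate the coding consequence of a variant key
#'
#' Uses the standard nuclear codon table in the declared frame. Multi-base
#' replacements within a codon are translated as a unit. Edits at the first or
#' last two intronic bases of an intron are labelled `splice_region`; variants
#' whose edits all fall outside exons are `intronic`.
#'
#' @param design an [amplicon_design()].
#' @param key a [variant_key()] (or bare edits data.frame).
#' @return list with `kind` (one of synonymous, missense, nonsense, intronic,
#'   splice_region), `aa_ref`, `aa_alt` (single-letter), `aa_pos`, `hgvs_p`.
#' @export
annotate_consequence <- function(design, key) {
  edits <- if (inherits(key, "variant_key")) key$edits else as.data.frame(key)
  maps <- lapply(edits$pos, map_position, design = design)
  offs <- vapply(maps, `[[`, integer(1), "offset")
  exonic <- offs == 0
  splice <- !exonic & abs(offs) <= 2
  if (!any(exonic)) {
    kind <- if (any(splice)) "splice_region" else "intronic"
    return(list(kind = kind, aa_ref = "", aa_alt = "", aa_pos = NA_integer_,
                hgvs_p = ""))
  }
  if (any(splice)) {
    return(list(kind = "splice_region", aa_ref = "", aa_alt = "",
                aa_pos = NA_integer_, hgvs_p = ""))
  }
  ex <- exonic_positions(design)
  cds <- strsplit(paste(substring(design$reference_seq, ex + 1, ex + 1),
                        collapse = ""), "")[[1]]
  mut <- cds
  ranks <- match(edits$pos[exonic], ex)
  mut[ranks] <- edits$alt[exonic]
  cdna <- design$cdna_offset + ranks
  codons <- sort(unique(ceiling(cdna / 3)))
  aa_ref <- aa_alt <- character(0)
  for (ci in codons) {
    cpos <- (3 * ci - 2):(3 * ci) - design$cdna_offset  # ranks in fragment
    if (any(cpos < 1 | cpos > length(cds)))
      stop("codon ", ci, " is not fully covered by the amplicon's exons")
    aa_ref <- c(aa_ref, translate_codon(paste(cds[cpos], collapse = "")))
    aa_alt <- c(aa_alt, translate_codon(paste(mut[cpos], collapse = "")))
  }
  if (any(aa_alt == "*")) {
    kind <- "nonsense"
  } else if (all(aa_ref == aa_alt)) {
    kind <- "synonymous"
  } else kind <- "missense"
  i <- which(aa_ref != aa_alt)[1]
  if (is.na(i)) i <- 1L
  hgvs_p <- paste0("p.", AA3[[aa_ref[i]]], codons[i],
                   if (aa_alt[i] == "*") "*" else AA3[[aa_alt[i]]])
  list(kind = kind, aa_ref = aa_ref[i], aa_alt = aa_alt[i],
       aa_pos = codons[i], hgvs_p = hgvs_p)
}

#' Enumerate the 63 non-wildtype codon replacements at one residue
#'
#' Emulates an NNN degenerate-codon ssODN library: every codon other than the
#' wildtype codon at the given residue, as variant keys whose edits are the
#' bases that differ from the reference.
#'
#' @param design an [amplicon_design()].
#' @param codon_index protein residue number (matching the c. numbering, i.e.
#'   residue `i` covers `c.(3i-2)` to `c.(3i)`).
#' @return list of 63 `variant_key` objects.
#' @export
enumerate_codon_library <- function(design, codon_index) {
  cdna <- (3 * codon_index - 2):(3 * codon_index)
  pos <- vapply(cdna, function(p) cdna_to_pos(design, p), integer(1))
  if (any(diff(pos) != 1))
    stop("codon ", codon_index, " spans an exon boundary; unsupported design")
  if (any(pos < design$target_region[1] | pos >= design$target_region[2]))
    stop("codon ", codon_index, " is not inside the target region")
  wt <- substring(design$reference_seq, pos + 1, pos + 1)
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    alt <- c(b1, b2, b3)
    if (all(alt == wt)) next
    diffi <- which(alt != wt)
    out[[length(out) + 1]] <- variant_key(
      design, data.frame(pos = pos[diffi], ref = wt[diffi], alt = alt[diffi]))
  }
  out
}

#' Enumerate all single-nucleotide variants across a region
#'
#' @param design an [amplicon_design()].
#' @param start,end region bounds, inclusive; either 0-based amplicon
#'   positions or HGVS c. labels such as `"c.6938-12"`.
#' @return list of `variant_key` objects, 3 per position.
#' @export
enumerate_snv_library <- function(design, start, end) {
  s <- resolve_position(design, start); e <- resolve_position(design, end)
  if (s > e) stop("inverted interval")
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (p in s:e) {
    if (p %in% design$marker_edits$pos) next
    ref <- substring(design$reference_seq, p + 1, p + 1)
    for (alt in setdiff(bases, ref)) {
      out[[length(out) + 1]] <- variant_key(
        design, data.frame(pos = p, ref = ref, alt = alt))
    }
  }
  out
}

#' Tabulate a variant library as a data.frame
#' @param library list of `variant_key` objects.
#' @return data.frame with `hgvs_c`, `hgvs_p`, `consequence` columns.
#' @export
library_table <- function(library) {
  data.frame(
    hgvs_c = vapply(library, `[[`, character(1), "hgvs_c"),
    hgvs_p = vapply(library, `[[`, character(1), "hgvs_p"),
    consequence = vapply(library, function(k) k$consequence$kind,
                         character(1)),
    stringsAsFactors = FALSE)
}

#' Read an amplicon design from a YAML configuration (plus optional FASTA)
#'
#' The YAML document carries the fields of [amplicon_design()]; the reference
#' sequence may be inline (`reference_seq`) or in a FASTA file
#' (`reference_fasta`, read with Biostrings).
#'
#' @param path YAML file path.
#' @return an [amplicon_design()].
#' @export
read_amplicon_design <- function(path) {
  if (!file.exists(path)) stop("design configuration not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$reference_seq)) {
    fa <- cfg$reference_fasta
    if (is.null(fa)) stop("config must give reference_seq or reference_fasta")
    if (!file.exists(fa))
      fa <- file.path(dirname(path), fa)
    if (!file.exists(fa)) stop("reference FASTA not found: ", cfg$reference_fasta)
    cfg$reference_seq <- as.character(Biostrings::readDNAStringSet(fa)[[1]])
  }
  me <- do.call(rbind, lapply(cfg$marker_edits, as.data.frame))
  amplicon_design(amplicon_id = cfg$amplicon_id,
                  reference_seq = cfg$reference_seq,
                  exon_intervals = cfg$exon_intervals,
                  cdna_offset = cfg$cdna_offset,
                  cut_sites = cfg$cut_sites,
                  marker_edits = me,
                  target_region = unlist(cfg$target_region),
                  cds_frame_offset = cfg$cds_frame_offset)
}

#' A small built-in demonstration design
#'
#' A 220-bp synthetic amplicon with a single 120-bp exon whose first base is
#' c.169 (so the exon covers residues 57-96), a blunt cut site just downstream
#' of the saturated codons, a synonymous HDR-marker edit in the PAM codon, and
#' a 3-codon saturation target (residues 57-59, mirroring a Tyr-Glu-Pro
#' stretch so that c.171C>A is the classic p.Tyr57* nonsense control).
#'
#' @return an [amplicon_design()].
#' @export
demo_design <- function() {
  flank5 <- "GATTACACGGCTAGCTTAGGCTGACCTTAAGCGGATCCAGTCAGGTACTC"   # 50 nt
  codons <- c("TAC", "GAA", "CCT",                       # Tyr57 Glu58 Pro59
              "GGT", "CTG", "AAC", "GAC", "TGC", "CTT",  # 60..65 (CTG@61 marker)
              "ATG", "TCA", "GGA", "CAT", "GTT", "ACC",  # 66..71
              "TTC", "AGT", "GCA", "AAG", "CGT", "GAG",  # 72..77
              "ATC", "CCA", "GGC", "TAT", "ACA", "GTG",  # 78..83
              "CTC", "AAT", "GAT", "TGG", "TCC", "CAA",  # 84..89
              "CAC", "TTG", "GCC", "AGA", "CGG", "ATT",  # 90..95
              "GTC")                                     # 96
  flank3 <- "GTAAGTACCTGATCGGCATTCCGGATATCAGGCTTAACGGATCCTGCACA"   # 50 nt
  ref <- paste0(flank5, paste(codons, collapse = ""), flank3)
  amplicon_design(
    amplicon_id = "demo_exon",
    reference_seq = ref,
    exon_intervals = rbind(c(50L, 170L)),
    cdna_offset = 168L,           # first exonic base is c.169
    cut_sites = 60L,              # blunt cut just after the target codons
    marker_edits = data.frame(pos = 64L, ref = "G", alt = "T"),  # CTG->CTT Leu61
    target_region = c(50L, 59L))  # residues 57-59
}
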