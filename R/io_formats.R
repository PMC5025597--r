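# Readers and validators for the standard inputs: somatic SNV catalogs
# (MAF-subset TSV or minimal single-sample VCF), reference FASTA, SEG-style
# segment tables, sample annotations and gene-level copy numbers. All
# coordinates are 1-based inclusive (MAF convention; VCF positions are
# already 1-based and used as-is).

MAF_COLUMNS <- c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
                 "Reference_Allele", "Tumor_Seq_Allele2")

#' Read a somatic mutation catalog
#'
#' Parses a MAF-subset TSV or a minimal VCF into a mutation table with one
#' row per single-nucleotide variant. Rows that are not simple SNVs (indels,
#' multi-base or multi-allelic records) are skipped, with the skipped count
#' reported via [message()]; they are never an error.
#'
#' @param path path to the file.
#' @param dialect `"maf"` or `"vcf"`. The MAF dialect requires columns
#'   `Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`,
#'   `Reference_Allele`, `Tumor_Seq_Allele2`. The VCF dialect holds one
#'   sample per file and needs `sample_id`.
#' @param sample_id sample identifier, required for the VCF dialect.
#' @return a `data.frame` with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, in input order.
#' @export
read_mutations <- function(path, dialect = c("maf", "vcf"), sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format("mutation file not found: %s", path)
  if (dialect == "maf") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             comment.char = "#", check.names = FALSE)
    missing <- setdiff(MAF_COLUMNS, names(tab))
    if (length(missing) > 0) {
      stop_format("MAF file %s is missing required column(s): %s",
                  path, paste(missing, collapse = ", "))
    }
    out <- data.frame(
      sample_id = as.character(tab$Tumor_Sample_Barcode),
      chrom = as.character(tab$Chromosome),
      pos = as.integer(tab$Start_Position),
      ref = toupper(as.character(tab$Reference_Allele)),
      alt = toupper(as.character(tab$Tumor_Seq_Allele2)),
      stringsAsFactors = FALSE
    )
  } else {
    if (is.null(sample_id)) {
      stop_format("VCF dialect requires a sample_id (one sample per file)")
    }
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    out <- data.frame(
      sample_id = rep(as.character(sample_id), nrow(fix)),
      chrom = as.character(fix[, "CHROM"]),
      pos = as.integer(fix[, "POS"]),
      ref = toupper(as.character(fix[, "REF"])),
      alt = toupper(as.character(fix[, "ALT"])),
      stringsAsFactors = FALSE
    )
  }
  is_snv <- out$ref %in% BASES & out$alt %in% BASES & out$ref != out$alt
  n_skip <- sum(!is_snv)
  if (n_skip > 0) {
    message(sprintf("read_mutations: skipped %d non-SNV record(s) in %s",
                    n_skip, path))
  }
  out <- out[is_snv, , drop = FALSE]
  rownames(out) <- NULL
  validate_mutations(out)
  out
}

validate_mutations <- function(mutations) {
  req <- c("sample_id", "chrom", "pos", "ref", "alt")
  missing <- setdiff(req, names(mutations))
  if (length(missing) > 0) {
    stop_format("mutation table is missing column(s): %s",
                paste(missing, collapse = ", "))
  }
  if (nrow(mutations) == 0) return(invisible(mutations))
  if (any(mutations$pos < 1)) stop_format("mutation positions must be >= 1")
  if (any(!mutations$ref %in% BASES) || any(!mutations$alt %in% BASES)) {
    stop_format("ref and alt must be single bases in A/C/G/T")
  }
  if (any(mutations$ref == mutations$alt)) {
    stop_format("ref and alt must differ (substitutions only)")
  }
  invisible(mutations)
}

#' Write a mutation table in the MAF-subset dialect
#'
#' Inverse of [read_mutations()] for the MAF dialect; re-reading the output
#' yields an identical record set.
#'
#' @param mutations mutation `data.frame`.
#' @param path output path.
#' @export
write_maf <- function(mutations, path) {
  validate_mutations(mutations)
  out <- data.frame(
    Tumor_Sample_Barcode = mutations$sample_id,
    Chromosome = mutations$chrom,
    Start_Position = mutations$pos,
    Reference_Allele = mutations$ref,
    Tumor_Seq_Allele2 = mutations$alt,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' Sequences are upper-cased and any character outside A/C/G/T/N becomes
#' `N`; `N` never matches a motif downstream. Record names are truncated at
#' the first whitespace.
#'
#' @param path FASTA path.
#' @return named character vector, one element per chromosome.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop_format("reference file not found: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  out <- gsub("[^ACGTN]", "N", out)
  out
}

#' Extract a context window around a position
#'
#' Returns `reference[pos - w .. pos + w]`, padded with `N` where the window
#' overhangs a chromosome end so the result always has length `2w + 1` and
#' per-mutation denominators stay comparable. The centre character is the
#' reference base at `pos`.
#'
#' @param reference named character vector of chromosome sequences.
#' @param chrom chromosome name.
#' @param pos 1-based position (may be a vector).
#' @param w half-width of the window (`w >= 1`).
#' @return character vector of windows, each of length `2w + 1`.
#' @export
fetch_context <- function(reference, chrom, pos, w) {
  if (w < 1) stop_format("window half-width w must be >= 1")
  if (!chrom %in% names(reference)) {
    stop_format("unknown chromosome: %s", chrom)
  }
  seq <- reference[[chrom]]
  len <- nchar(seq)
  if (any(pos < 1 | pos > len)) {
    stop_format("position outside [1, %d] on %s", len, chrom)
  }
  lo <- pmax(1L, pos - w)
  hi <- pmin(len, pos + w)
  core <- substring(seq, lo, hi)
  left <- strrep("N", lo - (pos - w))
  right <- strrep("N", (pos + w) - hi)
  paste0(left, core, right)
}

#' Read a SEG-style copy-number segment table
#'
#' Expects a TSV with columns `sample`, `chrom`, `start`, `end`, `value`.
#' `value` is either an absolute copy number or a log2 ratio; the encoding
#' is an explicit flag because SEG files in the wild use both. Log2 ratios
#' are converted as `copy_number = ploidy * 2^value`, which requires per-
#' sample ploidy.
#'
#' @param path SEG TSV path.
#' @param value_type `"copy_number"` (absolute) or `"log2ratio"`.
#' @param ploidy named numeric vector (sample -> ploidy) or a single value;
#'   required when `value_type = "log2ratio"`.
#' @return a `data.frame` with columns `sample_id`, `chrom`, `start`, `end`,
#'   `copy_number`, sorted by sample, chromosome and start.
#' @export
read_segments <- function(path, value_type = c("copy_number", "log2ratio"),
                          ploidy = NULL) {
  value_type <- match.arg(value_type)
  if (!file.exists(path)) stop_format("segment file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample", "chrom", "start", "end", "value")
  missing <- setdiff(req, names(tab))
  if (length(missing) > 0) {
    stop_format("segment file %s is missing column(s): %s",
                path, paste(missing, collapse = ", "))
  }
  seg <- data.frame(
    sample_id = as.character(tab$sample),
    chrom = as.character(tab$chrom),
    start = as.integer(tab$start),
    end = as.integer(tab$end),
    copy_number = as.numeric(tab$value),
    stringsAsFactors = FALSE
  )
  if (any(seg$end < seg$start)) {
    bad <- which(seg$end < seg$start)[1]
    stop_format("segment with end < start at row %d (%s %s:%d-%d)",
                bad, seg$sample_id[bad], seg$chrom[bad],
                seg$start[bad], seg$end[bad])
  }
  if (value_type == "log2ratio") {
    if (is.null(ploidy)) {
      stop_format("log2ratio segments require a ploidy to convert to copy number")
    }
    pl <- if (length(ploidy) == 1 && is.null(names(ploidy))) {
      rep(as.numeric(ploidy), nrow(seg))
    } else {
      unknown <- setdiff(unique(seg$sample_id), names(ploidy))
      if (length(unknown) > 0) {
        stop_format("no ploidy supplied for sample(s): %s",
                    paste(unknown, collapse = ", "))
      }
      as.numeric(ploidy[seg$sample_id])
    }
    seg$copy_number <- pl * 2^seg$copy_number
  }
  if (any(seg$copy_number < 0)) stop_format("negative copy number in %s", path)
  validate_segments(seg)
}

#' Validate and sort a segment table
#'
#' Sorts per sample and chromosome by start and errors on overlapping
#' segments, naming the offending sample and chromosome.
#'
#' @param segments segment `data.frame` as from [read_segments()].
#' @return the sorted `data.frame`.
#' @export
validate_segments <- function(segments) {
  ord <- order(segments$sample_id, segments$chrom, segments$start)
  seg <- segments[ord, , drop = FALSE]
  rownames(seg) <- NULL
  if (nrow(seg) > 1) {
    same <- seg$sample_id[-1] == seg$sample_id[-nrow(seg)] &
      seg$chrom[-1] == seg$chrom[-nrow(seg)]
    overlap <- same & seg$start[-1] <= seg$end[-nrow(seg)]
    if (any(overlap)) {
      i <- which(overlap)[1] + 1
      stop_format("overlapping segments for sample %s on %s",
                  seg$sample_id[i], seg$chrom[i])
    }
  }
  seg
}

#' Read sample annotations (subtype and ploidy)
#'
#' @param path TSV with columns `sample_id`, `subtype`, `ploidy`. Subtypes
#'   must be one of HER2, Basal, LumA, LumB, Normal; ploidy must be > 0.
#' @return validated `data.frame`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_format("annotation file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "subtype", "ploidy")
  missing <- setdiff(req, names(tab))
  if (length(missing) > 0) {
    stop_format("annotation file %s is missing column(s): %s",
                path, paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(tab$subtype), SUBTYPE_LEVELS)
  if (length(bad) > 0) {
    stop_format("unknown subtype label(s): %s (expected %s)",
                paste(bad, collapse = ", "),
                paste(SUBTYPE_LEVELS, collapse = ", "))
  }
  if (any(!is.finite(tab$ploidy)) || any(tab$ploidy <= 0)) {
    stop_format("ploidy must be a positive number for every sample")
  }
  if (anyDuplicated(tab$sample_id)) {
    stop_format("duplicated sample_id in annotations")
  }
  tab[, req]
}

#' Read a gene-level copy-number table
#'
#' @param path TSV with columns `gene`, `sample_id`, `copy_number`; one
#'   value per (gene, sample) pair.
#' @return validated `data.frame`.
#' @export
read_gene_cn <- function(path) {
  if (!file.exists(path)) stop_format("gene copy-number file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "sample_id", "copy_number")
  missing <- setdiff(req, names(tab))
  if (length(missing) > 0) {
    stop_format("gene copy-number file %s is missing column(s): %s",
                path, paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab[, c("gene", "sample_id")])) {
    stop_format("duplicated (gene, sample) pair in gene copy-number table")
  }
  if (any(!is.finite(tab$copy_number)) || any(tab$copy_number < 0)) {
    stop_format("gene copy numbers must be non-negative")
  }
  tab[, req]
}
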