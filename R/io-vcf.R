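#' Extract copy-number losses from a VCF
#'
#' Keeps only records whose ALT alleles include the symbolic loss alleles
#' `<CN0>` or `<DEL>`, the loss definition used for sequencing-based
#' structural-variant releases. Record spans follow the VCF structural
#' variant convention: `POS` is the base before the event and `INFO/END` its
#' last base (1-based), so the deleted interval is `(POS, END]`, converted
#' here to the package's 0-based half-open `[POS, END)`.
#'
#' If the file carries genotype columns, one call is emitted per sample whose
#' genotype includes a loss allele (`copy_state` is `"hom"` when every called
#' allele is a loss allele, `"het"` otherwise). A sites-only file yields one
#' sample-agnostic call per record (`sample_id = "*"`).
#'
#' Records with a loss ALT but no resolvable `END` (and no `SVLEN`) are
#' skipped with a warning.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param source_label Source label for the resulting callset.
#' @param assembly_tag Assembly label recorded on the callset.
#' @return A [cnv_callset()] tibble.
#' @export
read_vcf_losses <- function(path, source_label = "1000g", assembly_tag = "hg19") {
  loss_alleles <- c("<CN0>", "<DEL>")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- cnv_callset(tibble(chrom = character(), start = double(), end = double()),
                       source = source_label, assembly_tag = assembly_tag)
  if (nrow(vcf@fix) == 0) return(empty)

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  alts <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  is_loss_rec <- vapply(alts, function(a) any(a %in% loss_alleles), logical(1))
  if (!any(is_loss_rec)) return(empty)

  pos <- as.double(fix$POS)
  end <- suppressWarnings(as.double(vcfR::extract.info(vcf, "END")))
  svlen <- suppressWarnings(as.double(vcfR::extract.info(vcf, "SVLEN")))
  end[is.na(end) & !is.na(svlen)] <- pos[is.na(end) & !is.na(svlen)] +
    abs(svlen[is.na(end) & !is.na(svlen)])

  unresolved <- is_loss_rec & is.na(end)
  if (any(unresolved)) {
    warn(sprintf("skipping %d loss record(s) with no resolvable END in %s",
                 sum(unresolved), path))
    is_loss_rec <- is_loss_rec & !is.na(end)
  }
  idx <- which(is_loss_rec)
  if (length(idx) == 0) return(empty)

  state_of <- function(a) if ("<CN0>" %in% a) "CN0" else "DEL"

  has_gt <- ncol(vcf@gt) > 1
  rows <- list()
  if (has_gt) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    samples <- colnames(gt)
    for (i in idx) {
      loss_codes <- which(alts[[i]] %in% loss_alleles) # 1-based ALT allele codes
      for (s in samples) {
        g <- gt[i, s]
        if (is.na(g)) next
        codes <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
        codes <- codes[!is.na(codes)]
        if (length(codes) == 0 || !any(codes %in% loss_codes)) next
        zyg <- if (all(codes %in% loss_codes)) "hom" else "het"
        rows[[length(rows) + 1L]] <- tibble(
          chrom = fix$CHROM[i], start = pos[i], end = end[i],
          sample_id = s, copy_state = zyg
        )
      }
    }
  } else {
    for (i in idx) {
      rows[[length(rows) + 1L]] <- tibble(
        chrom = fix$CHROM[i], start = pos[i], end = end[i],
        sample_id = "*", copy_state = state_of(alts[[i]])
      )
    }
  }
  if (length(rows) == 0) return(empty)
  cnv_callset(bind_rows(rows), source = source_label, assembly_tag = assembly_tag)
}
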