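# Readers and writers for the plain-text interchange formats the pipeline
# uses: 6-column PED, VCF 4.2 genotype tables (GT/DP/GQ/PS), BED intervals
# (0-based half-open) and TRGT-style tandem-repeat TSVs. VCF positions are
# 1-based on disk and converted to 0-based half-open internally where
# intervals are needed. Malformed records are reported with line numbers.

provenanceHeader <- function(seed = NA, extra = "") {
  ver <- tryCatch(as.character(utils::packageVersion("pedDNM")),
                  error = function(e) "dev")
  sprintf("# pedDNM %s; seed=%s%s", ver, seed,
          if (nzchar(extra)) paste0("; ", extra) else "")
}

#' Write and read a 6-column PED file
#'
#' Columns: family, individual, father, mother, sex (1 = male, 2 = female),
#' phenotype (0 = missing). Unknown parents are written as "0".
#'
#' @param ped a [Pedigree-class].
#' @param path file path.
#' @param family family id used on write.
#' @return `readPed()` returns a [Pedigree-class]; generations are inferred
#'   from parental depth when absent from the file.
#' @export
writePed <- function(ped, path, family = "FAM1") {
  m <- members(ped)
  df <- data.frame(family = family, id = m$id,
                   father = ifelse(is.na(m$father), "0", m$father),
                   mother = ifelse(is.na(m$mother), "0", m$mother),
                   sex = ifelse(m$sex == "M", 1L, 2L), phenotype = 0L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writePed
#' @export
readPed <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "", header = FALSE, col.names = c(
      "family", "id", "father", "mother", "sex", "phenotype"),
      colClasses = c(rep("character", 4L), "integer", "character")),
    error = function(e) stop("malformed PED file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  m <- data.frame(id = df$id, sex = ifelse(df$sex == 1L, "M", "F"),
                  generation = NA_integer_,
                  father = ifelse(df$father == "0", NA, df$father),
                  mother = ifelse(df$mother == "0", NA, df$mother),
                  stringsAsFactors = FALSE)
  # infer generation as 1 + longest ancestor chain
  depth <- function(id, seen = character()) {
    r <- m[m$id == id, ]
    if (is.na(r$father)) return(1L)
    if (id %in% seen) stop("pedigree cycle at ", id, call. = FALSE)
    1L + max(depth(r$father, c(seen, id)), depth(r$mother, c(seen, id)))
  }
  m$generation <- vapply(m$id, depth, 1L)
  # spouses sit in their partner's generation
  for (i in which(is.na(m$father))) {
    kids <- m$id[!is.na(m$father) &
                   (m$father == m$id[i] | m$mother == m$id[i])]
    if (length(kids))
      m$generation[i] <- max(m$generation[i],
                             min(m$generation[match(kids, m$id)]) - 1L)
  }
  Pedigree(m)
}

#' Write and read a minimal genotype VCF (v4.2)
#'
#' Writes site records with GT (optionally phased with PS), DP and GQ FORMAT
#' fields; reads them back into a long table. Positions are 1-based in the
#' file, per the format.
#'
#' @param sites data.frame(chrom, pos, ref, alt).
#' @param gt matrix of genotype strings (sites x samples), e.g. "0/1" or
#'   "1|0".
#' @param path file path.
#' @param dp,gq,ps optional matrices matching `gt`.
#' @param seed seed recorded in the header provenance line.
#' @return `readVcfTable()` returns list(sites, gt, dp, gq, ps) with the
#'   same shapes.
#' @export
writeVcfTable <- function(sites, gt, path, dp = NULL, gq = NULL, ps = NULL,
                          seed = NA) {
  samples <- colnames(gt)
  fmt <- c("GT", if (!is.null(dp)) "DP", if (!is.null(gq)) "GQ",
           if (!is.null(ps)) "PS")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=", provenanceHeader(seed)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
               '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
               '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (i in seq_len(nrow(sites))) {
    cells <- vapply(seq_along(samples), function(j) {
      paste(c(gt[i, j], if (!is.null(dp)) dp[i, j],
              if (!is.null(gq)) gq[i, j], if (!is.null(ps)) ps[i, j]),
            collapse = ":")
    }, "")
    writeLines(paste(c(sites$chrom[i], sites$pos[i], ".",
                       sites$ref[i], sites$alt[i], ".", "PASS", ".",
                       paste(fmt, collapse = ":"), cells), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' @rdname writeVcfTable
#' @export
readVcfTable <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  hdrIdx <- grep("^#CHROM", lines)
  if (!length(hdrIdx)) stop("malformed VCF ", path, ": no #CHROM header")
  hdr <- strsplit(lines[hdrIdx], "\t")[[1L]]
  samples <- hdr[-(1:9)]
  body <- lines[-seq_len(hdrIdx)]
  body <- body[nzchar(body)]
  if (!length(body))
    return(list(sites = data.frame(chrom = character(), pos = integer(),
                                   ref = character(), alt = character()),
                gt = NULL, dp = NULL, gq = NULL, ps = NULL))
  parts <- strsplit(body, "\t")
  bad <- which(lengths(parts) != length(hdr))
  if (length(bad))
    stop("malformed VCF record at line ", hdrIdx + bad[1L], " of ", path)
  mat <- do.call(rbind, parts)
  sites <- data.frame(chrom = mat[, 1L], pos = as.integer(mat[, 2L]),
                      ref = mat[, 4L], alt = mat[, 5L],
                      stringsAsFactors = FALSE)
  fmt <- strsplit(mat[, 9L], ":")
  field <- function(name) {
    out <- matrix(NA_character_, nrow = nrow(mat), ncol = length(samples),
                  dimnames = list(NULL, samples))
    for (i in seq_len(nrow(mat))) {
      k <- match(name, fmt[[i]])
      if (is.na(k)) next
      out[i, ] <- vapply(strsplit(mat[i, -(1:9)], ":"), `[`, "", k)
    }
    if (all(is.na(out))) NULL else out
  }
  asInt <- function(x) if (is.null(x)) NULL else
    matrix(as.integer(x), nrow = nrow(x), dimnames = dimnames(x))
  list(sites = sites, gt = field("GT"), dp = asInt(field("DP")),
       gq = asInt(field("GQ")), ps = asInt(field("PS")))
}

#' Write and read BED intervals (0-based half-open)
#'
#' @param gr a [GenomicRanges::GRanges] or data.frame(chrom, start, end)
#'   with 0-based half-open coordinates.
#' @param path file path.
#' @return `readBed()` returns a GRanges (1-based internal coordinates, per
#'   the container's convention).
#' @export
writeBed <- function(gr, path) {
  df <- if (is(gr, "GRanges"))
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr))
  else gr
  utils::write.table(df[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeBed
#' @export
readBed <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = c("character", "integer", "integer"))[, 1:3],
    error = function(e) stop("malformed BED file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  names(df) <- c("chrom", "start", "end")
  df$chrom <- sub("\r$", "", df$chrom)
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end))
}

#' Write and read a TRGT-style tandem-repeat genotype TSV
#'
#' Columns: locus, chrom, start, end (0-based half-open), motifs
#' (comma-separated), sample, al1, al2, and optionally a comma-separated
#' list of per-read allele lengths.
#'
#' @param catalog TR catalog data.frame.
#' @param genotypes TR genotype data.frame (sample, locus, al1, al2).
#' @param path file path.
#' @param seed provenance seed.
#' @return `readTrTsv()` returns list(catalog, genotypes).
#' @export
writeTrTsv <- function(catalog, genotypes, path, seed = NA) {
  g <- merge(genotypes,
             catalog[, c("locus", "chrom", "start", "end", "motifs")],
             by = "locus", sort = FALSE)
  g <- g[, c("locus", "chrom", "start", "end", "motifs", "sample",
             "al1", "al2")]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(provenanceHeader(seed), con)
  utils::write.table(g, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrTsv
#' @export
readTrTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("locus", "chrom", "start", "end", "motifs", "sample", "al1", "al2")
  if (!all(need %in% names(df)))
    stop("malformed TR TSV ", path, ": need columns ",
         paste(need, collapse = ", "))
  catalog <- unique(df[, c("locus", "chrom", "start", "end", "motifs")])
  catalog$refLen <- catalog$end - catalog$start
  catalog$minMotif <- vapply(strsplit(catalog$motifs, ","), function(x)
    min(nchar(x)), 1L)
  rownames(catalog) <- NULL
  list(catalog = catalog,
       genotypes = df[, c("sample", "locus", "al1", "al2")])
}
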