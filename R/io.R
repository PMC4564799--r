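#' Read a multi-record FASTA file
#'
#' Sequences are case-normalized to upper case; gaps (`-`) and IUPAC
#' ambiguity codes are kept verbatim. Record order follows file order.
#'
#' @param path Path to a FASTA file.
#' @return A named list of sequence strings (names are the first whitespace
#'   token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("not a FASTA file (first line lacks '>'): ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(gsub("\\s", "", x), collapse = "")),
                 character(1))
  if (length(seqs) != length(ids) || any(!nzchar(seqs)))
    stop("FASTA record with empty sequence in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  bad <- grepl("[^ACGTUMRWSYKVHDBN?-]", seqs)
  if (any(bad)) stop("non-IUPAC characters in record(s): ",
                     paste(ids[bad], collapse = ", "))
  stats::setNames(as.list(seqs), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named list or character vector of sequence strings.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- unlist(seqs)
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a GenBank flat file
#'
#' Parses the ORIGIN sequence and gene/CDS/tRNA/rRNA features. Feature
#' coordinates are converted from GenBank 1-based inclusive to 0-based
#' half-open at parse time (the single conversion point for the package);
#' `join()` locations yield one row per segment sharing a `feature_id`.
#' Trans-spliced features (join segments out of order or mixed strand) are
#' dropped with a warning.
#'
#' @param path Path to a GenBank flat file.
#' @return A list with `id` (accession), `seq` (upper-case sequence string),
#'   and `features`, a data.frame with columns `feature_id`, `type`, `start`,
#'   `end` (0-based half-open), `strand` (`"+"`/`"-"`), `gene`.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("GenBank file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^LOCUS", lines))) stop("not a GenBank flat file: ", path)
  if (!any(grepl("^//\\s*$", lines))) stop("truncated GenBank record (no // terminator): ", path)
  acc <- sub("^ACCESSION\\s+(\\S+).*$", "\\1", grep("^ACCESSION", lines, value = TRUE)[1])
  if (is.na(acc)) acc <- sub("^LOCUS\\s+(\\S+).*$", "\\1", grep("^LOCUS", lines, value = TRUE)[1])

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0L) stop("GenBank record has no ORIGIN block: ", path)
  endrec <- grep("^//\\s*$", lines)[1]
  seq <- toupper(paste(gsub("[^A-Za-z]", "", lines[(ostart[1] + 1L):(endrec - 1L)]),
                       collapse = ""))
  if (!nzchar(seq)) stop("GenBank record has an empty sequence: ", path)

  feats <- list()
  if (length(fstart)) {
    flines <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    # a feature starts at indent 5 with a type token; continuation lines at 21
    is_new <- grepl("^\\s{5}\\S", flines)
    idx <- cumsum(is_new)
    keep_types <- c("gene", "CDS", "tRNA", "rRNA")
    fid <- 0L
    for (block in split(flines, idx)) {
      type <- sub("^\\s+(\\S+).*$", "\\1", block[1])
      if (!(type %in% keep_types)) next
      # location may continue over lines until a /qualifier appears
      qual_at <- grep("^\\s{21}/", block)
      loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
      loc <- paste(gsub("\\s", "", sub("^\\s+\\S+\\s*", "", block[1])),
                   paste(gsub("\\s", "", block[seq_len(loc_end)[-1]]), collapse = ""),
                   sep = "")
      gene <- NA_character_
      g <- grep("/gene=", block, value = TRUE)
      if (length(g)) {
        mm <- regmatches(g[1], regexec('/gene="?([^"]+)"?', g[1]))[[1]]
        if (length(mm) == 2) gene <- mm[2]
      }
      seg <- parse_genbank_location(loc)
      if (is.null(seg)) {
        warning("trans-spliced or unparsable location dropped (", type, " ", loc, ")")
        next
      }
      fid <- fid + 1L
      feats[[fid]] <- data.frame(feature_id = fid, type = type,
                                 start = seg$start, end = seg$end,
                                 strand = seg$strand, gene = gene,
                                 stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(feature_id = integer(), type = character(), start = integer(),
               end = integer(), strand = character(), gene = character())
  if (nrow(features) && max(features$end) > nchar(seq))
    stop("feature coordinates exceed sequence length in ", path)
  list(id = acc, seq = seq, features = features)
}

# Parse a GenBank location string into 0-based half-open segments.
# Supports n..m, complement(...), join(...); returns NULL for locations that
# look trans-spliced (non-monotone join) or that it cannot parse.
parse_genbank_location <- function(loc) {
  strand <- "+"
  x <- loc
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x)) x <- sub("^join\\((.*)\\)$", "\\1", x)
  if (grepl("complement|join|order", x)) return(NULL)  # nested => trans-spliced
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  rng <- regmatches(parts, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", parts))
  single <- regmatches(parts, regexec("^(\\d+)$", parts))
  lo <- hi <- integer(length(parts))
  for (i in seq_along(parts)) {
    if (length(rng[[i]]) == 3L) {
      lo[i] <- as.integer(rng[[i]][2]); hi[i] <- as.integer(rng[[i]][3])
    } else if (length(single[[i]]) == 2L) {
      lo[i] <- hi[i] <- as.integer(single[[i]][2])
    } else return(NULL)
  }
  if (any(hi < lo)) return(NULL)
  if (length(lo) > 1L && any(diff(lo) < 0)) return(NULL)  # out-of-order join
  list(start = lo - 1L, end = hi, strand = strand)
}

#' Build a coding/noncoding/intergenic partition from GenBank features
#'
#' `coding` is the union of CDS segments; `intergenic` is the complement of
#' all gene/CDS/tRNA/rRNA spans; `noncoding` is what remains (introns, UTRs
#' and structural RNA within annotated spans).
#'
#' @param features Feature data.frame from [read_genbank()].
#' @param genome_length Sequence length in bp.
#' @return A [partition_set()] over `[0, genome_length)`.
#' @export
features_to_partition <- function(features, genome_length) {
  ir_of <- function(df) {
    if (nrow(df) == 0L) return(IRanges::IRanges())
    IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
  }
  cds <- ir_of(features[features$type == "CDS", , drop = FALSE])
  anyf <- ir_of(features)
  full <- IRanges::IRanges(1L, genome_length)
  intergenic <- IRanges::setdiff(full, anyf)
  noncoding <- IRanges::setdiff(IRanges::setdiff(full, cds), intergenic)
  as_mat <- function(ir) cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  partition_set(list(coding = as_mat(cds), noncoding = as_mat(noncoding),
                     intergenic = as_mat(intergenic)),
                n_columns = genome_length)
}

#' Create a partition set over alignment columns
#'
#' Intervals are 0-based half-open; partitions must be pairwise disjoint and
#' within bounds. Columns left unassigned are implicitly a default partition.
#'
#' @param partitions Named list; each element a 2-column matrix (`start`,
#'   `end`) of 0-based half-open intervals.
#' @param n_columns Total number of alignment columns.
#' @return An object of class `partition_set`.
#' @export
partition_set <- function(partitions, n_columns) {
  stopifnot(is.list(partitions), !is.null(names(partitions)),
            all(nzchar(names(partitions))), n_columns >= 1)
  seen <- integer(0)
  for (nm in names(partitions)) {
    m <- partitions[[nm]]
    if (length(m) == 0L) { partitions[[nm]] <- cbind(start = integer(), end = integer()); next }
    m <- matrix(as.integer(m), ncol = 2, dimnames = list(NULL, c("start", "end")))
    if (any(m[, 1] < 0) || any(m[, 2] > n_columns) || any(m[, 2] <= m[, 1]))
      stop("partition '", nm, "' has intervals outside [0, ", n_columns, ") or empty")
    cols <- unlist(lapply(seq_len(nrow(m)), function(i) seq(m[i, 1], m[i, 2] - 1L)))
    if (any(cols %in% seen)) stop("partitions overlap at partition '", nm, "'")
    seen <- c(seen, cols)
    partitions[[nm]] <- m
  }
  structure(list(partitions = partitions, n_columns = as.integer(n_columns)),
            class = "partition_set")
}

#' Column indices (1-based) covered by one partition
#' @param ps A [partition_set()].
#' @param name Partition name.
#' @return Integer vector of 1-based column indices.
#' @export
partition_columns <- function(ps, name) {
  stopifnot(inherits(ps, "partition_set"))
  m <- ps$partitions[[name]]
  if (is.null(m)) stop("no partition named '", name, "'")
  if (nrow(m) == 0L) return(integer(0))
  sort(unlist(lapply(seq_len(nrow(m)), function(i) seq(m[i, 1] + 1L, m[i, 2]))))
}

#' Read partition definitions from a NEXUS sets block or a flat charset file
#'
#' Accepts `charset name = 1-100 200-300;` lines (coordinates 1-based
#' inclusive, the NEXUS convention) anywhere in the file.
#'
#' @param path File containing charset lines.
#' @param n_columns Alignment width the partition refers to.
#' @return A [partition_set()].
#' @export
read_charsets <- function(path, n_columns) {
  lines <- readLines(path, warn = FALSE)
  cs <- grep("charset", lines, ignore.case = TRUE, value = TRUE)
  if (length(cs) == 0L) stop("no charset lines found in ", path)
  parts <- list()
  for (l in cs) {
    l <- sub(";\\s*$", "", trimws(l))
    nm <- sub("(?i)^charset\\s+(\\S+)\\s*=.*$", "\\1", l, perl = TRUE)
    body <- sub("^[^=]*=\\s*", "", l)
    toks <- strsplit(trimws(body), "\\s+")[[1]]
    ivs <- t(vapply(toks, function(tok) {
      if (grepl("-", tok)) as.integer(strsplit(tok, "-")[[1]][1:2])
      else rep(as.integer(tok), 2L)
    }, integer(2)))
    parts[[nm]] <- cbind(start = ivs[, 1] - 1L, end = ivs[, 2])
  }
  partition_set(parts, n_columns)
}

#' Read / write Newick trees
#'
#' Thin wrappers around the ape parser, kept so every module goes through one
#' I/O surface. `read_newick` accepts a file path or a literal Newick string.
#'
#' @param x Newick string or path to a file containing one.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(x) {
  txt <- if (file.exists(x)) paste(readLines(x, warn = FALSE), collapse = "") else x
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    stop("unbalanced parentheses in Newick (", n_open, " '(' vs ", n_close, " ')')")
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick: ", substr(txt, 1, 60))
  tr
}

#' @rdname read_newick
#' @param tree An `ape::phylo` tree.
#' @param path Optional output file; if `NULL` the string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Align sequences with an external MAFFT (convenience hook)
#'
#' Shells out to `mafft` if present on the PATH. The tested pipeline consumes
#' pre-aligned FASTA; this hook only exists so unaligned inputs can be pushed
#' through the same entry points.
#'
#' @param seqs Named list of unaligned sequence strings.
#' @param mafft_args Extra command-line arguments.
#' @return Named list of aligned sequences.
#' @export
align_with_mafft <- function(seqs, mafft_args = "--auto") {
  if (Sys.which("mafft") == "") stop("mafft not found on PATH")
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)))
  write_fasta(seqs, fin)
  status <- system2("mafft", c(mafft_args, shQuote(fin)), stdout = fout,
                    stderr = FALSE)
  if (status != 0L) stop("mafft exited with status ", status)
  read_fasta(fout)
}
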