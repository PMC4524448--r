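# Synthetic, truth-annotated data generation.
#
# The simulator emulates what a transcript-counting library looks like
# after sequencing: a toy genome with non-overlapping transcripts whose
# 3'-downstream context is A-poor (true polyA sites) except at planted
# internal misprime sites with rule-matching A-rich contexts; read
# pairs with the read-1 tag structure (UMI + index + spacer + polyT),
# PCR duplicates as exact copies sharing a UMI, i.i.d. substitution
# errors, and a two-condition negative-binomial count structure with
# known fold changes.  Reads are emitted both as FASTQ and as
# pre-aligned SAM (with the tags already in the read name), so the
# pipeline can be exercised without an external aligner.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is validated
#' under: 50 transcripts over 2 contigs, 6 samples per condition,
#' baseline expression log-normal with median 260 read pairs per
#' transcript per sample (about 200k pairs in total), negative-binomial
#' dispersion 0.1, a 2% PCR duplication rate, 5 internal misprime
#' sites, fragment lengths uniform on 70-270 bases and a 0.001
#' substitution error rate.
#'
#' @param seed integer seed making every output reproducible.
#' @param nContigs,nTranscripts genome layout.
#' @param exprMeanlog,exprSdlog log-normal baseline expression
#'   (expected read pairs per transcript per sample).
#' @param dispersion negative-binomial dispersion of molecule counts.
#' @param nPerCondition samples per condition (two conditions).
#' @param fcFraction,fcValue fraction of transcripts given a true fold
#'   change, alternating \code{fcValue} and \code{1/fcValue}
#'   (condition 2 over condition 1).
#' @param duplicationRate expected fraction of read pairs that are PCR
#'   duplicate copies.
#' @param misprimeCount planted internal misprime sites.
#' @param misprimeMeanReads expected read pairs per misprime site per
#'   sample.
#' @param backgroundRate fraction of additional scattered noise pairs.
#' @param errorRate per-base substitution probability.
#' @param read1Length,read2Length,polyTLength,fragmentRange read
#'   geometry.
#' @param spikes when TRUE, 92 single-transcript spike contigs with a
#'   descending abundance ladder are added and the sample conditions
#'   become the four spike tiers (x5, x1, x0.2, x0.1) in
#'   \code{nPerCondition = 3} replicates.
#' @param spikeTiers named tier multipliers.
#' @param nSpikes number of spike contigs.
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L, nContigs = 2L, nTranscripts = 50L,
                      exprMeanlog = log(260), exprSdlog = 0.7,
                      dispersion = 0.1, nPerCondition = 6L,
                      fcFraction = 0.2, fcValue = 4,
                      duplicationRate = 0.02, misprimeCount = 5L,
                      misprimeMeanReads = 80, backgroundRate = 0.01,
                      errorRate = 0.001, read1Length = 75L,
                      read2Length = 54L, polyTLength = 14L,
                      fragmentRange = c(70L, 270L), spikes = FALSE,
                      spikeTiers = c(x5 = 5, x1 = 1, x0.2 = 0.2,
                                     x0.1 = 0.1),
                      nSpikes = 92L) {
    cfg <- as.list(environment())
    rates <- c(cfg$duplicationRate, cfg$backgroundRate, cfg$errorRate,
               cfg$fcFraction)
    stopifnot(all(rates >= 0 & rates <= 1),
              cfg$nTranscripts >= 0L, cfg$nPerCondition >= 1L,
              cfg$dispersion > 0,
              cfg$fragmentRange[1L] <= cfg$fragmentRange[2L])
    class(cfg) <- "SimConfig"
    cfg
}

fastRandomDna <- function(n, len, bases = c("A", "C", "G", "T")) {
    if (n == 0L) return(character())
    do.call(paste0, lapply(seq_len(len), function(i)
        sample(bases, n, replace = TRUE)))
}

# Replace the n bases of `replacement` starting at `at` in contig
# string `contig` (character scalar).
spliceIn <- function(contig, at, replacement) {
    paste0(substr(contig, 1L, at - 1L), replacement,
           substring(contig, at + nchar(replacement)))
}

misprimeContext <- function(rule) {
    switch(rule,
        start = paste0("AAAA", paste(sample(c("C", "G", "T"), 6L,
                                            replace = TRUE),
                                     collapse = "")),
        total = {  # seven As, not starting AAAA
            repeat {
                s <- paste(sample(c(rep("A", 7L),
                                    sample(c("C", "G", "T"), 3L,
                                           replace = TRUE))),
                           collapse = "")
                if (substr(s, 1L, 4L) != "AAAA") break
            }
            s
        },
        pattern = {
            pat <- sample(POLYA_PATTERNS, 1L)
            chars <- strsplit(pat, "")[[1L]]
            paste(ifelse(chars == "A", "A",
                         sample(c("C", "G", "T"), 10L, replace = TRUE)),
                  collapse = "")
        })
}

#' Simulate a toy genome and its transcript annotation
#'
#' Transcripts are laid out left to right with intergenic gaps, strands
#' alternating.  The 10 bases immediately 3' of every true transcript
#' end (in transcript orientation, outside the transcript) are drawn
#' from {C, G, T} so no artifact rule can fire on a true end; each
#' planted misprime site overwrites the 10 bases 3' of an internal
#' position with a context matching one of the three artifact rules.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{genome} (\code{DNAStringSet}),
#'   \code{annotation} (data frame as \code{\link{readAnnotation}}),
#'   \code{transcripts} (truth: coordinates, baseline expression, true
#'   fold change) and \code{misprimes} (truth: position, strand,
#'   context rule).
#' @export
simulateGenomeAndAnnotation <- function(config) {
    set.seed(config$seed)
    nTx <- config$nTranscripts
    txLen <- if (nTx) round(stats::runif(nTx, 800, 1600)) else integer()
    gaps <- if (nTx) round(stats::runif(nTx, 1200, 2500)) else integer()
    contig <- if (nTx) rep(seq_len(config$nContigs), length.out = nTx) else integer()
    contig <- sort(contig)
    strand <- rep(c("+", "-"), length.out = nTx)

    txStart <- integer(nTx)
    txEnd <- integer(nTx)
    contigLen <- integer(config$nContigs)
    for (ci in seq_len(config$nContigs)) {
        at <- 1000L
        for (i in which(contig == ci)) {
            txStart[i] <- at
            txEnd[i] <- at + txLen[i] - 1L
            at <- txEnd[i] + gaps[i]
        }
        contigLen[ci] <- at + 1000L
    }
    contigNames <- paste0("chr", seq_len(config$nContigs))
    genome <- vapply(contigLen, function(l)
        paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
              collapse = ""), character(1L))
    names(genome) <- contigNames

    threePrime <- ifelse(strand == "+", txEnd, txStart)
    # A-poor context 3' of every true end, outside the transcript
    for (i in seq_len(nTx)) {
        ctx <- paste(sample(c("C", "G", "T"), 10L, replace = TRUE),
                     collapse = "")
        ci <- contig[i]
        if (strand[i] == "+") {
            genome[ci] <- spliceIn(genome[ci], threePrime[i] + 1L, ctx)
        } else {
            genome[ci] <- spliceIn(genome[ci], threePrime[i] - 10L,
                                   revComp(ctx))
        }
    }

    fc <- rep(1, nTx)
    nFc <- round(config$fcFraction * nTx)
    if (nFc > 0L) {
        who <- sample(seq_len(nTx), nFc)
        fc[who] <- rep(c(config$fcValue, 1 / config$fcValue),
                       length.out = nFc)
    }
    baseline <- stats::rlnorm(nTx, config$exprMeanlog, config$exprSdlog)

    ids <- sprintf("tx%03d", seq_len(nTx))
    transcripts <- data.frame(
        transcript_id = ids, chromosome = contigNames[contig],
        strand = strand, tx_start = txStart, tx_end = txEnd,
        three_prime_end = threePrime, baseline = baseline,
        fold_change = fc)

    # misprime sites: internal positions in the longest transcripts,
    # with A-rich downstream contexts written into the genome
    nMp <- min(config$misprimeCount, nTx)
    misprimes <- data.frame(misprime_id = character(),
                            transcript_id = character(),
                            chromosome = character(),
                            position = integer(), strand = character(),
                            rule = character())
    if (nMp > 0L) {
        host <- order(txLen, decreasing = TRUE)[seq_len(nMp)]
        rules <- rep(c("start", "total", "pattern"), length.out = nMp)
        mpPos <- integer(nMp)
        for (j in seq_len(nMp)) {
            i <- host[j]
            # keep 200 bases clear of both transcript ends
            off <- round(stats::runif(1L, 200, txLen[i] - 200))
            ctx <- misprimeContext(rules[j])
            ci <- contig[i]
            if (strand[i] == "+") {
                mpPos[j] <- txStart[i] + off
                genome[ci] <- spliceIn(genome[ci], mpPos[j] + 1L, ctx)
            } else {
                mpPos[j] <- txEnd[i] - off
                genome[ci] <- spliceIn(genome[ci], mpPos[j] - 10L,
                                       revComp(ctx))
            }
        }
        misprimes <- data.frame(
            misprime_id = sprintf("mp%02d", seq_len(nMp)),
            transcript_id = ids[host], chromosome = contigNames[contig[host]],
            position = mpPos, strand = strand[host], rule = rules)
    }

    annotation <- data.frame(
        transcript_id = ids,
        gene_id = sprintf("gene%03d", seq_len(nTx)),
        gene_name = sprintf("g%03d", seq_len(nTx)),
        chromosome = contigNames[contig], strand = strand,
        three_prime_end = threePrime,
        biotype = rep("protein_coding", nTx))

    if (config$spikes) {
        spk <- simulateSpikeContigs(config)
        genome <- c(genome, spk$genome)
        annotation <- rbind(annotation, spk$annotation)
        transcripts <- rbind(transcripts, spk$transcripts)
    }

    list(genome = Biostrings::DNAStringSet(genome),
         annotation = annotation, transcripts = transcripts,
         misprimes = misprimes)
}

# 92 single-transcript spike contigs with a descending abundance
# ladder (fold_change = 1; the tier multiplier is applied per sample).
simulateSpikeContigs <- function(config) {
    n <- config$nSpikes
    len <- round(stats::runif(n, 600, 1200))
    genome <- vapply(len + 400L, function(l)
        paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
              collapse = ""), character(1L))
    names(genome) <- sprintf("spike%02d", seq_len(n))
    txStart <- rep(201L, n)
    txEnd <- 200L + len
    for (i in seq_len(n)) {
        ctx <- paste(sample(c("C", "G", "T"), 10L, replace = TRUE),
                     collapse = "")
        genome[i] <- spliceIn(genome[i], txEnd[i] + 1L, ctx)
    }
    ids <- sprintf("spiketx%02d", seq_len(n))
    baseline <- 2^seq(11, -4, length.out = n)  # abundance-ranked ladder
    list(genome = genome,
         annotation = data.frame(
             transcript_id = ids, gene_id = ids, gene_name = ids,
             chromosome = names(genome), strand = "+",
             three_prime_end = txEnd, biotype = "spike_in"),
         transcripts = data.frame(
             transcript_id = ids, chromosome = names(genome),
             strand = "+", tx_start = txStart, tx_end = txEnd,
             three_prime_end = txEnd, baseline = baseline,
             fold_change = 1))
}

simSampleSheet <- function(config) {
    if (config$spikes) {
        tiers <- names(config$spikeTiers)
        condition <- rep(tiers, each = config$nPerCondition)
    } else {
        condition <- rep(c("cond1", "cond2"),
                         each = config$nPerCondition)
    }
    n <- length(condition)
    data.frame(sample = sprintf("s%02d", seq_len(n)),
               condition = condition)
}

# Deterministically build an index whitelist with pairwise Hamming
# distance >= 3 (greedy over random candidates; RNG state is the
# caller's).
simIndexWhitelist <- function(n, len = 8L) {
    out <- character(0L)
    while (length(out) < n) {
        cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      collapse = "")
        if (!length(out) || min(hammingToOne(out, cand)) >= 3L)
            out <- c(out, cand)
    }
    names(out) <- sprintf("s%02d", seq_len(n))
    out
}

addSubstitutionErrors <- function(seqs, rate) {
    if (rate <= 0) return(seqs)
    nerr <- stats::rbinom(length(seqs), nchar(seqs), rate)
    for (i in which(nerr > 0L)) {
        s <- strsplit(seqs[i], "")[[1L]]
        pos <- sample(length(s), nerr[i])
        s[pos] <- vapply(s[pos], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
        seqs[i] <- paste(s, collapse = "")
    }
    seqs
}

#' Simulate tagged read pairs
#'
#' Draws per-sample molecule counts for every transcript and misprime
#' site from a negative binomial, lays a fragment ending at the
#' (true or misprimed) 3' end, emits read 1 as
#' UMI + index + spacer + polyT + antisense 3'-flank and read 2 as the
#' sense sequence at the fragment's far end, adds exact duplicate
#' copies sharing the UMI, applies substitution errors, and returns
#' both FASTQ-style records and pre-aligned SAM records (read names
#' already carrying UMI and index) together with a read-level truth
#' table.
#'
#' @param config a \code{\link{simConfig}}.
#' @param sim output of \code{\link{simulateGenomeAndAnnotation}}
#'   (regenerated from \code{config} when omitted).
#' @param outDir optional directory; when given, writes
#'   \code{reads_1.fastq}, \code{reads_2.fastq}, \code{aligned.sam},
#'   \code{genome.fa}, \code{annotation.tsv}, \code{truth.tsv} and
#'   \code{samples.tsv}.
#' @return list with \code{fastq} (pair data frame as
#'   \code{\link{readFastqPairs}}), \code{sam} (record data frame as
#'   \code{\link{readSam}}), \code{truth} (read-level origins),
#'   \code{samples}, \code{layout} (the \linkS4class{TagLayout} used,
#'   whitelist included) and the \code{sim} truth objects.
#' @export
simulateReads <- function(config, sim = NULL, outDir = NULL) {
    if (is.null(sim)) sim <- simulateGenomeAndAnnotation(config)
    set.seed(config$seed + 1L)
    genome <- as.character(sim$genome)
    samples <- simSampleSheet(config)
    nS <- nrow(samples)
    whitelist <- simIndexWhitelist(nS)
    layout <- tagLayout(indexWhitelist = whitelist)

    tx <- sim$transcripts
    mp <- sim$misprimes
    # per-sample tier multipliers (spike design) or condition fold
    # changes (two-condition design)
    sampleMult <- function(txRow, cond) {
        if (config$spikes && startsWith(txRow$transcript_id, "spiketx"))
            config$spikeTiers[[cond]]
        else if (!config$spikes && cond == "cond2")
            txRow$fold_change
        else 1
    }

    origin <- list()
    for (si in seq_len(nS)) {
        cond <- samples$condition[si]
        for (ti in seq_len(nrow(tx))) {
            mu <- tx$baseline[ti] * sampleMult(tx[ti, ], cond)
            n <- stats::rnbinom(1L, mu = mu, size = 1 / config$dispersion)
            if (n > 0L)
                origin[[length(origin) + 1L]] <- data.frame(
                    sample = samples$sample[si], condition = cond,
                    origin = "transcript",
                    origin_id = tx$transcript_id[ti],
                    chromosome = tx$chromosome[ti],
                    strand = tx$strand[ti],
                    end_pos = tx$three_prime_end[ti],
                    max_frag = tx$tx_end[ti] - tx$tx_start[ti] + 1L,
                    n = n)
        }
        for (mi in seq_len(nrow(mp))) {
            hostRow <- tx[match(mp$transcript_id[mi], tx$transcript_id), ]
            n <- stats::rnbinom(1L, mu = config$misprimeMeanReads,
                                size = 1 / config$dispersion)
            room <- if (mp$strand[mi] == "+")
                mp$position[mi] - hostRow$tx_start + 1L
            else hostRow$tx_end - mp$position[mi] + 1L
            if (n > 0L)
                origin[[length(origin) + 1L]] <- data.frame(
                    sample = samples$sample[si], condition = cond,
                    origin = "misprime", origin_id = mp$misprime_id[mi],
                    chromosome = mp$chromosome[mi],
                    strand = mp$strand[mi], end_pos = mp$position[mi],
                    max_frag = room, n = n)
        }
        nNoise <- stats::rpois(1L, config$backgroundRate *
                                   sum(tx$baseline))
        if (nNoise > 0L && config$nTranscripts > 0L) {
            ci <- sample(seq_along(genome), nNoise, replace = TRUE)
            len <- nchar(genome)[ci]
            pos <- round(stats::runif(nNoise, 400, len - 400))
            origin[[length(origin) + 1L]] <- data.frame(
                sample = samples$sample[si], condition = cond,
                origin = "noise",
                origin_id = sprintf("noise_%s_%d", names(genome)[ci], pos),
                chromosome = names(genome)[ci],
                strand = sample(c("+", "-"), nNoise, replace = TRUE),
                end_pos = pos, max_frag = 300L, n = 1L)
        }
    }
    origin <- do.call(rbind, origin)
    mol <- origin[rep(seq_len(nrow(origin)), origin$n), , drop = FALSE]
    nMol <- nrow(mol)
    rownames(mol) <- NULL
    mol$n <- NULL

    fragMax <- pmax(pmin(mol$max_frag, config$fragmentRange[2L]),
                    config$fragmentRange[1L])
    mol$frag_len <- pmin(round(stats::runif(nMol, config$fragmentRange[1L],
                                            config$fragmentRange[2L])),
                         fragMax)
    mol$umi <- fastRandomDna(nMol, layout@umiLength)

    # duplicate copies: exact copies sharing UMI and coordinates
    q <- config$duplicationRate / max(1 - config$duplicationRate, 1e-9)
    copies <- 1L + stats::rbinom(nMol, 1L, min(q, 1))
    mol$duplicate_group <- seq_len(nMol)
    reads <- mol[rep(seq_len(nMol), copies), , drop = FALSE]
    reads$is_duplicate_copy <- duplicated(reads$duplicate_group)
    rownames(reads) <- NULL
    nR <- nrow(reads)
    ord <- sample(nR)   # shuffle so duplicates are not adjacent
    reads <- reads[ord, , drop = FALSE]
    reads$read_id <- sprintf("sim%07d", seq_len(nR))

    ins1 <- pmin(config$read1Length - layout@umiLength -
                 layout@indexLength - nchar(layout@spacer) -
                 config$polyTLength, reads$frag_len)
    len2 <- pmin(config$read2Length, reads$frag_len)
    plus <- reads$strand == "+"
    # read-1 aligned span (antisense of the transcript 3' flank)
    r1start <- ifelse(plus, reads$end_pos - ins1 + 1L, reads$end_pos)
    r1end <- ifelse(plus, reads$end_pos, reads$end_pos + ins1 - 1L)
    # fragment far end carries read 2 (sense)
    fragFar <- ifelse(plus, reads$end_pos - reads$frag_len + 1L,
                      reads$end_pos + reads$frag_len - 1L)
    r2start <- ifelse(plus, fragFar, fragFar - len2 + 1L)
    r2end <- ifelse(plus, fragFar + len2 - 1L, fragFar)

    contigSeq <- genome[reads$chromosome]
    r1ref <- substr(contigSeq, r1start, r1end)
    r2ref <- substr(contigSeq, r2start, r2end)
    # as-sequenced orientation: read 1 is reverse-complemented on '+'
    # transcripts, read 2 on '-' transcripts
    r1seq <- ifelse(plus, revComp(r1ref), r1ref)
    r2seq <- ifelse(plus, r2ref, revComp(r2ref))

    # apply errors to unique molecules, then copy exactly
    firstOfGroup <- !reads$is_duplicate_copy
    r1seq[firstOfGroup] <- addSubstitutionErrors(r1seq[firstOfGroup],
                                                 config$errorRate)
    r2seq[firstOfGroup] <- addSubstitutionErrors(r2seq[firstOfGroup],
                                                 config$errorRate)
    fix <- match(reads$duplicate_group, reads$duplicate_group[firstOfGroup])
    r1seq <- r1seq[which(firstOfGroup)[fix]]
    r2seq <- r2seq[which(firstOfGroup)[fix]]
    # mismatch counts against the reference
    countMm <- function(obs, ref) {
        out <- integer(length(obs))
        diff <- obs != ref
        for (i in which(diff))
            out[i] <- sum(utf8ToInt(obs[i]) != utf8ToInt(ref[i]))
        out
    }
    nm1 <- countMm(ifelse(plus, revComp(r1seq), r1seq), r1ref)
    nm2 <- countMm(ifelse(plus, r2seq, revComp(r2seq)), r2ref)

    index <- whitelist[reads$sample]
    # the tag prefix sees sequencing errors too (exercising index/UMI
    # handling); applied per molecule so duplicate copies stay exact
    prefix <- paste0(reads$umi, index, layout@spacer,
                     strrep("T", config$polyTLength))
    prefix[firstOfGroup] <- addSubstitutionErrors(prefix[firstOfGroup],
                                                  config$errorRate)
    prefix <- prefix[which(firstOfGroup)[fix]]
    r1full <- paste0(prefix, r1seq)
    fastq <- data.frame(
        pair_id = reads$read_id,
        sequence1 = r1full, qualities1 = strrep("I", nchar(r1full)),
        sequence2 = r2seq, qualities2 = strrep("I", nchar(r2seq)))

    qname <- renameWithTags(reads$read_id, reads$umi, index)
    tlen <- pmax(r1end, r2end) - pmin(r1start, r2start) + 1L
    samR1 <- data.frame(
        qname = qname, flag = 0L, rname = reads$chromosome,
        pos = r1start, mapq = 60L, cigar = paste0(ins1, "M"),
        rnext = "=", pnext = r2start, tlen = ifelse(plus, -tlen, tlen),
        seq = ifelse(plus, revComp(r1seq), r1seq),
        qual = strrep("I", ins1), nm = nm1,
        paired = TRUE, unmapped = FALSE, mate_unmapped = FALSE,
        reverse = plus, mate_reverse = !plus, read1 = TRUE,
        read2 = FALSE, duplicate = FALSE)
    samR2 <- data.frame(
        qname = qname, flag = 0L, rname = reads$chromosome,
        pos = r2start, mapq = 60L, cigar = paste0(len2, "M"),
        rnext = "=", pnext = r1start, tlen = ifelse(plus, tlen, -tlen),
        seq = ifelse(plus, r2seq, revComp(r2seq)),
        qual = strrep("I", len2), nm = nm2,
        paired = TRUE, unmapped = FALSE, mate_unmapped = FALSE,
        reverse = !plus, mate_reverse = plus, read1 = FALSE,
        read2 = TRUE, duplicate = FALSE)
    sam <- rbind(samR1, samR2)
    sam <- sam[order(sam$rname, sam$pos), , drop = FALSE]
    sam$flag <- encodeSamFlag(sam$paired, sam$unmapped,
                              sam$mate_unmapped, sam$reverse,
                              sam$mate_reverse, sam$read1, sam$read2,
                              sam$duplicate)
    attr(sam, "header") <- c("@HD\tVN:1.6\tSO:coordinate",
                             paste0("@SQ\tSN:", names(genome),
                                    "\tLN:", nchar(genome)))

    truth <- data.frame(
        read_id = reads$read_id, sample = reads$sample,
        condition = reads$condition, origin = reads$origin,
        origin_id = reads$origin_id, chromosome = reads$chromosome,
        strand = reads$strand, true_end = reads$end_pos,
        umi = reads$umi, duplicate_group = reads$duplicate_group,
        is_duplicate_copy = reads$is_duplicate_copy)

    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeFastq(paste0(fastq$pair_id, "/1"), fastq$sequence1,
                   fastq$qualities1, file.path(outDir, "reads_1.fastq"))
        writeFastq(paste0(fastq$pair_id, "/2"), fastq$sequence2,
                   fastq$qualities2, file.path(outDir, "reads_2.fastq"))
        writeSam(sam, file.path(outDir, "aligned.sam"))
        Biostrings::writeXStringSet(sim$genome,
                                    file.path(outDir, "genome.fa"))
        writeAnnotation(sim$annotation,
                        file.path(outDir, "annotation.tsv"))
        utils::write.table(truth, file.path(outDir, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        samplesOut <- samples
        samplesOut$index <- whitelist[samples$sample]
        utils::write.table(samplesOut, file.path(outDir, "samples.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(fastq = fastq, sam = sam, truth = truth, samples = samples,
         layout = layout, sim = sim)
}

#' Simulate a region count matrix directly
#'
#' Desk-scale shortcut feeding the differential stage without reads:
#' negative-binomial counts with log-normal baseline means, per-sample
#' depth factors, and a true log2 fold-change vector (condition 2 over
#' condition 1).
#'
#' @param nRegions number of regions.
#' @param nPerCondition samples per condition.
#' @param meanlog,sdlog log-normal baseline mean parameters.
#' @param dispersion negative-binomial dispersion.
#' @param log2FC true per-region log2 fold changes, recycled (default
#'   0: a null dataset).
#' @param depthFactors per-sample depth multipliers (default 1).
#' @param seed RNG seed.
#' @return list with \code{counts}, \code{condition} and
#'   \code{trueLog2FC}.
#' @export
simulateCounts <- function(nRegions = 1000L, nPerCondition = 6L,
                           meanlog = log(100), sdlog = 1,
                           dispersion = 0.1, log2FC = 0,
                           depthFactors = NULL, seed = 1L) {
    set.seed(seed)
    condition <- factor(rep(c("cond1", "cond2"), each = nPerCondition))
    nS <- length(condition)
    if (is.null(depthFactors)) depthFactors <- rep(1, nS)
    stopifnot(length(depthFactors) == nS)
    baseMean <- stats::rlnorm(nRegions, meanlog, sdlog)
    trueLfc <- rep_len(log2FC, nRegions)
    mu <- matrix(baseMean, nRegions, nS)
    is2 <- condition == "cond2"
    mu[, is2] <- mu[, is2] * 2^trueLfc
    mu <- sweep(mu, 2L, depthFactors, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / dispersion),
                     nrow = nRegions,
                     dimnames = list(NULL, sprintf("s%02d", seq_len(nS))))
    list(counts = counts, condition = condition, trueLog2FC = trueLfc)
}

#' Simulate the spike-tier count design
#'
#' 92 spike regions with a descending abundance ladder, measured under
#' four concentration tiers (x5, x1, x0.2, x0.1) in triplicate — the
#' design used to benchmark fold-change recovery across all six
#' pairwise tier comparisons.  The spikes sit in a background of host
#' regions whose abundance does not change across tiers, mirroring a
#' spike mix added to a constant total-RNA pool; without that anchor,
#' median-of-ratios normalisation would absorb the global tier
#' multiplier and no spike fold change would be observable.
#'
#' @param nSpikes number of spike regions.
#' @param tiers named tier multipliers.
#' @param replicates samples per tier.
#' @param dispersion negative-binomial dispersion (technical
#'   replicates, default 0.05).
#' @param topMean mean count of the most abundant spike at tier x1.
#' @param nHost constant host regions anchoring normalisation.
#' @param hostMeanlog,hostSdlog log-normal host abundance parameters.
#' @param seed RNG seed.
#' @return list with \code{counts} ((spikes + host) x samples),
#'   \code{condition} (tier factor), \code{isSpike} (row mask) and
#'   \code{baseMean} (x1 spike ladder).
#' @export
simulateSpikeCounts <- function(nSpikes = 92L,
                                tiers = c(x5 = 5, x1 = 1, x0.2 = 0.2,
                                          x0.1 = 0.1),
                                replicates = 3L, dispersion = 0.05,
                                topMean = 4096, nHost = 2000L,
                                hostMeanlog = log(200), hostSdlog = 1,
                                seed = 1L) {
    set.seed(seed)
    condition <- factor(rep(names(tiers), each = replicates),
                        levels = names(tiers))
    ladder <- topMean * 2^seq(0, -15, length.out = nSpikes)
    hostMean <- stats::rlnorm(nHost, hostMeanlog, hostSdlog)
    mu <- rbind(outer(ladder, tiers[as.character(condition)]),
                matrix(hostMean, nHost, length(condition)))
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / dispersion),
                     nrow = nrow(mu),
                     dimnames = list(
                         c(sprintf("spike%02d", seq_len(nSpikes)),
                           sprintf("host%04d", seq_len(nHost))),
                         sprintf("s%02d", seq_along(condition))))
    list(counts = counts, condition = condition,
         isSpike = c(rep(TRUE, nSpikes), rep(FALSE, nHost)),
         baseMean = ladder)
}

#' Simulate a binned coverage track with planted enriched intervals
#'
#' Poisson background with planted higher-rate intervals, for
#' exercising the peak caller against known truth.
#'
#' @param nBins track length in bins.
#' @param lambda0,lambda1 background and enriched Poisson means.
#' @param nIntervals planted intervals.
#' @param intervalBins bins per interval (recycled).
#' @param seed RNG seed.
#' @return list with \code{track} (named list with one count vector)
#'   and \code{intervals} (data frame \code{first}, \code{last}).
#' @export
simulateBinTrack <- function(nBins = 2000L, lambda0 = 0.5,
                             lambda1 = 10, nIntervals = 3L,
                             intervalBins = 4L, seed = 1L) {
    set.seed(seed)
    x <- stats::rpois(nBins, lambda0)
    width <- rep_len(intervalBins, nIntervals)
    gap <- nBins %/% (nIntervals + 1L)
    first <- gap * seq_len(nIntervals) -
        round(stats::runif(nIntervals, 0, gap / 4))
    last <- first + width - 1L
    for (i in seq_len(nIntervals))
        x[first[i]:last[i]] <- stats::rpois(width[i], lambda1)
    list(track = list(chr1 = x),
         intervals = data.frame(first = first, last = last))
}
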