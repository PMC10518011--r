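# Shared fixture builders. Everything is generated in code; nothing binary
# ships with the package.

# a tiny guide library with deterministic spacers
tiny_guides <- function(n = 3) {
  spacers <- vapply(seq_len(n), function(i) {
    set.seed(1000 + i)
    paste0("G", paste0(sample(c("A", "C", "G", "T"), 19, replace = TRUE),
                       collapse = ""))
  }, character(1))
  tibble::tibble(
    guide_id = paste0("guide", seq_len(n)),
    spacer = spacers,
    target_gene = paste0("GENE", seq_len(n)),
    targeting = TRUE
  )
}

tiny_reference <- function(n = 3, upstream = "AAACCC", scaffold = "GGGTTTAAC") {
  build_custom_reference(
    tiny_guides(n),
    cassette_template(c(upstream = upstream, spacer = "", scaffold = scaffold))
  )
}

# hand-build a tagged read tibble row
mk_read <- function(cell_barcode, umi, contig, seq, pos = 0L,
                    cigar = paste0(nchar(seq), "M"), flag = 0L,
                    guide_annotation = contig,
                    qname = paste0("q", cell_barcode, umi, sample(1e6, 1))) {
  tibble::tibble(qname = qname, flag = flag, contig = contig, pos = pos,
                 cigar = cigar, seq = seq, cell_barcode = cell_barcode,
                 umi = umi, guide_annotation = guide_annotation)
}

# independent per-base oracle: apply an event list to a reference and return
# the sequence the aligned read should have over its span (no skips/clips)
apply_events_oracle <- function(refseq, events, pos, ref_span) {
  # walk reference bases [pos, pos + ref_span); substitute / delete / insert
  out <- character(0)
  i <- pos
  events <- events[order(events$position), , drop = FALSE]
  while (i < pos + ref_span) {
    ev <- events[!is.na(events$position) & events$position == i, , drop = FALSE]
    ins <- ev[ev$kind == "insertion", , drop = FALSE]
    for (k in seq_len(nrow(ins))) out <- c(out, ins$alt[k])
    del <- ev[ev$kind %in% c("deletion", "skip"), , drop = FALSE]
    if (nrow(del) > 0) {
      i <- i + nchar(del$ref[1])
      next
    }
    sub <- ev[ev$kind == "substitution", , drop = FALSE]
    if (nrow(sub) > 0) {
      out <- c(out, sub$alt[1])
    } else {
      out <- c(out, substr(refseq, i + 1, i + 1))
    }
    i <- i + 1
  }
  # trailing insertions anchored at the span end
  ev <- events[events$kind == "insertion" & events$position == pos + ref_span, ,
               drop = FALSE]
  for (k in seq_len(nrow(ev))) out <- c(out, ev$alt[k])
  paste0(out, collapse = "")
}

# brute-force plurality consensus oracle over a read multiset
plurality_oracle <- function(seqs) {
  tab <- table(seqs)
  winners <- names(tab)[tab == max(tab)]
  list(winners = winners, support = max(tab))
}
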