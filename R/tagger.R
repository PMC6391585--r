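#' Read a corpus of documents
#'
#' Two layouts are supported: a JSONL file with one object per line
#' (`{"doc_id": ..., "text": ...}`), or a directory of plain `.txt` files
#' whose file name (without extension) is the document id.
#'
#' @param path Path to a `.jsonl` file or a directory of `.txt` files.
#' @return Tibble with columns `doc_id`, `text`.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    return(tibble::tibble(
      doc_id = tools::file_path_sans_ext(basename(files)),
      text = vapply(files, function(f)
        paste(readLines(f, warn = FALSE), collapse = "\n"), character(1))
    ))
  }
  recs <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
  tb <- tibble::tibble(
    doc_id = vapply(recs, `[[`, character(1), "doc_id"),
    text = vapply(recs, `[[`, character(1), "text")
  )
  if (anyDuplicated(tb$doc_id)) {
    stop("duplicate doc_id in corpus: ", tb$doc_id[duplicated(tb$doc_id)][1L],
         call. = FALSE)
  }
  tb
}

# Abbreviations after which a period never ends a sentence.
sentence_abbreviations <- c(
  "fig", "figs", "dr", "mr", "mrs", "ms", "prof", "vs", "etc", "al", "st",
  "ca", "approx", "ref", "refs", "eq", "eqs", "cf", "resp", "min", "max",
  "e.g", "i.e", "inc", "ltd", "dept", "univ", "ed", "eds", "vol", "suppl"
)

#' Split a document into sentences
#'
#' Rule-based splitter: a sentence ends at a run of terminal punctuation
#' (`.`, `!`, `?`, optionally followed by a closing quote or bracket) that is
#' followed by whitespace and then an uppercase letter, digit or opening
#' quote — unless the token immediately before a period is a known
#' abbreviation ("Fig.", "et al.", "e.g." ...). The returned sentences are
#' exact substrings of the input: their concatenation reconstructs the text.
#'
#' @param text A single character string.
#' @return Character vector of sentences (exact substrings, in order).
#' @examples
#' split_sentences("Mutation of Icam5 caused encephalitis. See Fig. 2 for AUC.")
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) return(character(0))
  m <- gregexpr("[.!?]+[\"')\\]]*\\s+", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(text)
  ends <- as.integer(m) + attr(m, "match.length") - 1L  # incl. trailing ws
  punct_start <- as.integer(m)
  keep <- logical(length(ends))
  for (i in seq_along(ends)) {
    nxt <- substr(text, ends[i] + 1L, ends[i] + 1L)
    if (!grepl("[A-Z0-9\"'(\\[]", nxt)) next
    # token before the punctuation run
    before <- substr(text, 1L, punct_start[i] - 1L)
    tok <- stringr::str_extract(before, "[A-Za-z][A-Za-z.]*$")
    punct <- substr(text, punct_start[i], punct_start[i])
    if (punct == "." && !is.na(tok) &&
        stringr::str_to_lower(tok) %in% sentence_abbreviations) next
    keep[i] <- TRUE
  }
  bounds <- c(0L, ends[keep], nchar(text))
  bounds <- unique(bounds)
  mapply(function(a, b) substr(text, a + 1L, b),
         bounds[-length(bounds)], bounds[-1L], USE.NAMES = FALSE)
}

#' Split every document of a corpus into indexed sentences
#'
#' @param corpus Tibble with columns `doc_id`, `text` (see [read_corpus()]).
#' @return Tibble with columns `doc_id`, `sentence_index` (0-based within
#'   document), `text`.
#' @export
corpus_sentences <- function(corpus) {
  stopifnot(all(c("doc_id", "text") %in% names(corpus)))
  sents <- lapply(corpus$text, split_sentences)
  tibble::tibble(
    doc_id = rep(corpus$doc_id, lengths(sents)),
    sentence_index = unlist(lapply(lengths(sents), function(n)
      seq_len(n) - 1L), use.names = FALSE),
    text = unlist(sents, use.names = FALSE)
  )
}

# tokenize a character vector of sentences into one long tibble:
# sent (row index), pos, token, start, end (1-based inclusive char positions)
tokenize_sentences <- function(texts) {
  m <- gregexpr("[A-Za-z0-9]+", texts)
  toks <- regmatches(texts, m)
  n <- lengths(toks)
  n[vapply(m, function(x) x[1L] == -1L, logical(1))] <- 0L
  starts <- unlist(lapply(m, function(x) if (x[1L] == -1L) integer(0) else as.integer(x)),
                   use.names = FALSE)
  lens <- unlist(lapply(m, function(x) if (x[1L] == -1L) integer(0) else
    attr(x, "match.length")), use.names = FALSE)
  tibble::tibble(
    sent = rep(seq_along(texts), n),
    pos = unlist(lapply(n, seq_len), use.names = FALSE),
    token = unlist(toks, use.names = FALSE),
    start = starts,
    end = starts + lens - 1L
  )
}

# all candidate dictionary matches of one lexicon against a token table
match_lexicon <- function(tokens, lexicon) {
  entries <- lexicon$entries
  if (!nrow(entries) || !nrow(tokens)) {
    return(tibble::tibble(sent = integer(0), start = integer(0), end = integer(0),
                          term = character(0), entity_id = character(0)))
  }
  res <- list()
  ord <- tokens  # already in (sent, pos) order by construction
  for (n in sort(unique(entries$n_tokens))) {
    if (n == 1L) {
      g <- tibble::tibble(sent = ord$sent, start = ord$start, end = ord$end,
                          phrase = ord$token)
    } else {
      lead_sent <- dplyr::lead(ord$sent, n - 1L)
      ok <- !is.na(lead_sent) & lead_sent == ord$sent
      phrase <- ord$token
      for (k in seq_len(n - 1L)) phrase <- paste(phrase, dplyr::lead(ord$token, k))
      g <- tibble::tibble(sent = ord$sent, start = ord$start,
                          end = dplyr::lead(ord$end, n - 1L), phrase = phrase)[ok, ]
    }
    g$phrase_lower <- stringr::str_to_lower(g$phrase)
    lex_n <- entries[entries$n_tokens == n, ]
    ci <- lex_n[!lex_n$case_sensitive, ]
    cs <- lex_n[lex_n$case_sensitive, ]
    hit_ci <- dplyr::inner_join(g, ci, by = c(phrase_lower = "term"),
                                relationship = "many-to-many")
    hit_cs <- dplyr::inner_join(g, cs, by = c(phrase = "term"),
                                relationship = "many-to-many")
    hit_ci$term <- hit_ci$phrase_lower
    hit_cs$term <- hit_cs$phrase
    res[[length(res) + 1L]] <- dplyr::bind_rows(hit_ci, hit_cs) %>%
      dplyr::select("sent", "start", "end", "term", "entity_id")
  }
  dplyr::bind_rows(res)
}

# greedy overlap resolution within each sentence: longest span wins, ties by
# leftmost start, then lexicographic term; all entity ids of a kept span
# survive (ambiguity is deferred to the statistics)
resolve_overlaps <- function(matches) {
  if (!nrow(matches)) return(matches)
  spans <- matches %>%
    dplyr::distinct(.data$sent, .data$start, .data$end, .data$term) %>%
    dplyr::arrange(.data$sent, .data$start, .data$end)
  # sentences whose spans already don't overlap skip the greedy pass
  flag <- spans %>%
    dplyr::group_by(.data$sent) %>%
    dplyr::mutate(clash = .data$start <= dplyr::lag(cummax(.data$end),
                                                    default = 0L)) %>%
    dplyr::summarise(any_clash = any(.data$clash), .groups = "drop")
  clean <- spans %>%
    dplyr::semi_join(dplyr::filter(flag, !.data$any_clash), by = "sent")
  dirty <- spans %>%
    dplyr::semi_join(dplyr::filter(flag, .data$any_clash), by = "sent")
  if (nrow(dirty)) {
    kept <- dirty %>%
      dplyr::arrange(.data$sent, -(.data$end - .data$start), .data$start,
                     .data$term) %>%
      dplyr::group_by(.data$sent) %>%
      dplyr::group_modify(function(df, key) {
        sel <- logical(nrow(df))
        occ_s <- integer(0); occ_e <- integer(0)
        for (i in seq_len(nrow(df))) {
          if (!any(df$start[i] <= occ_e & df$end[i] >= occ_s)) {
            sel[i] <- TRUE
            occ_s <- c(occ_s, df$start[i]); occ_e <- c(occ_e, df$end[i])
          }
        }
        df[sel, ]
      }) %>%
      dplyr::ungroup()
    clean <- dplyr::bind_rows(clean, kept)
  }
  matches %>%
    dplyr::semi_join(clean, by = c("sent", "start", "end", "term")) %>%
    dplyr::arrange(.data$sent, .data$start, .data$entity_id)
}

#' Tag gene and phenotype mentions in sentences
#'
#' Dictionary-based named entity recognition: sentences are reduced to their
#' alphanumeric token stream and every n-gram is looked up in the gene and
#' phenotype dictionaries (case-insensitively, except short all-uppercase
#' gene symbols which must match exactly). Matches must start and end at
#' token boundaries. Overlapping matches of the same kind are resolved
#' greedily — longest span first, then leftmost, then lexicographic term —
#' and a term mapping to several entity ids emits one mention per id.
#'
#' @param sentences Tibble with columns `doc_id`, `sentence_index`, `text`
#'   (see [corpus_sentences()]), or a character vector of sentences.
#' @param gene_lexicon,phenotype_lexicon [phenomine_lexicon] objects; either
#'   may be `NULL` to skip that kind.
#' @return Tibble of mentions: `doc_id`, `sentence_index`, `kind` (`"gene"`
#'   or `"phenotype"`), `entity_id`, `term`, `start`, `end`. Spans are
#'   0-based half-open `[start, end)` over the sentence string. Sentences
#'   with no mentions contribute no rows.
#' @export
tag_sentences <- function(sentences, gene_lexicon = NULL,
                          phenotype_lexicon = NULL) {
  if (is.character(sentences)) {
    sentences <- tibble::tibble(doc_id = "doc", sentence_index = seq_along(sentences) - 1L,
                                text = sentences)
  }
  stopifnot(all(c("doc_id", "sentence_index", "text") %in% names(sentences)))
  tokens <- tokenize_sentences(sentences$text)
  one_kind <- function(lex, kind) {
    if (is.null(lex)) return(NULL)
    stopifnot(inherits(lex, "phenomine_lexicon"))
    m <- resolve_overlaps(match_lexicon(tokens, lex))
    if (!nrow(m)) return(NULL)
    dplyr::mutate(m, kind = kind)
  }
  hits <- dplyr::bind_rows(one_kind(gene_lexicon, "gene"),
                           one_kind(phenotype_lexicon, "phenotype"))
  if (is.null(hits) || !nrow(hits)) {
    return(tibble::tibble(doc_id = character(0), sentence_index = integer(0),
                          kind = character(0), entity_id = character(0),
                          term = character(0), start = integer(0), end = integer(0)))
  }
  hits %>%
    dplyr::transmute(
      doc_id = sentences$doc_id[.data$sent],
      sentence_index = sentences$sentence_index[.data$sent],
      .data$kind, .data$entity_id, .data$term,
      start = .data$start - 1L,  # to 0-based half-open
      end = .data$end
    ) %>%
    dplyr::arrange(.data$doc_id, .data$sentence_index, .data$start,
                   .data$kind, .data$entity_id)
}

#' @rdname tag_sentences
#' @param text A single sentence string.
#' @export
tag_sentence <- function(text, gene_lexicon = NULL, phenotype_lexicon = NULL) {
  tag_sentences(text, gene_lexicon, phenotype_lexicon)
}

#' Write tagged sentences to JSONL
#'
#' One JSON object per sentence with its gene and phenotype mentions
#' (entity id plus 0-based half-open character span).
#'
#' @param sentences Sentence tibble (see [corpus_sentences()]).
#' @param mentions Mention tibble from [tag_sentences()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tagged_jsonl <- function(sentences, mentions, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(sentences))) {
    mm <- mentions[mentions$doc_id == sentences$doc_id[i] &
                     mentions$sentence_index == sentences$sentence_index[i], ]
    rec <- list(
      doc_id = sentences$doc_id[i],
      sentence_index = sentences$sentence_index[i],
      text = sentences$text[i],
      gene_mentions = mm[mm$kind == "gene", c("entity_id", "start", "end")],
      phenotype_mentions = mm[mm$kind == "phenotype", c("entity_id", "start", "end")]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, dataframe = "rows"), con)
  }
  invisible(path)
}
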