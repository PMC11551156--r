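# Synthetic variety-report corpus generator.
#
# Emulates the structure of wheat-variety approval prose: each sentence
# names one variety (the head entity) followed by several attribute
# clauses whose values (unit-bearing numbers or trait words) are the tail
# entities -- so every sentence carries single-entity-overlap triples.
# Romanized template tokens keep fixtures readable while the model still
# operates purely at character level; a Chinese-token mode is available.

variety_prefixes <- function(chinese = FALSE) {
  if (chinese) {
    c("中麦", "矮麦", "济麦", "豫麦",
      "鲁麦", "皖麦", "周麦", "新麦")
  } else {
    c("Zhongmai", "Aimai", "Jimai", "Yumai", "Lumai", "Wanmai",
      "Zhoumai", "Xinmai")
  }
}

# Built-in attribute inventory: one entry per relation of the default
# schema. `keyword` introduces the clause; numeric attributes get a value
# drawn in `range` with `dec` decimals plus `unit`; categorical ones draw
# a value from `cats`.
attribute_specs <- function(chinese = FALSE) {
  num <- function(label, kw, kwz, range, dec, unit) {
    list(label = label, keyword = if (chinese) kwz else kw, type = "num",
         range = range, dec = dec, unit = unit)
  }
  cat_ <- function(label, kw, kwz, cats, catsz) {
    list(label = label, keyword = if (chinese) kwz else kw, type = "cat",
         cats = if (chinese) catsz else cats)
  }
  list(
    num("Growth period", "shengyuqi", "生育期",
        c(180, 245), 0, "day"),
    cat_("Winter-spring type", "dongchunxing", "冬春性",
         c("winter", "semiwinter", "spring"),
         c("冬性", "半冬性", "春性")),
    num("Plant height", "zhugao", "株高", c(60, 110), 1, "cm"),
    cat_("Maturity", "shoushuqi", "成熟期",
         c("early", "medium", "late"),
         c("早熟", "中熟", "晚熟")),
    num("Spike number per mu", "muhsuishu", "亩穗数",
        c(30, 50), 1, "wan/mu"),
    cat_("Shell color", "kese", "壳色",
         c("white", "red"), c("白壳", "红壳")),
    num("Kernel number", "suilishu", "穗粒数",
        c(28, 44), 0, "grain"),
    cat_("Seed color", "lise", "粒色",
         c("white", "red", "amber"),
         c("白粒", "红粒", "琥珀色")),
    num("1000-grain weight", "qianlizhong", "千粒重",
        c(35, 56), 1, "g"),
    cat_("Grain hardness", "yingdu", "硬度",
         c("hard", "soft", "mixed"),
         c("硬质", "软质", "混合")),
    num("Unit weight", "rongzhong", "容重", c(750, 850), 0, "g/L"),
    cat_("Grain shape", "lixing", "粒型",
         c("oval", "round", "longoval"),
         c("椭圆", "圆形", "长椭圆")),
    num("Stability time", "wendingshijian", "稳定时间",
        c(2, 13), 1, "min"),
    cat_("Awn length", "mangchang", "芒长",
         c("longawn", "shortawn", "awnless"),
         c("长芒", "短芒", "无芒")),
    num("Tensile area", "lashenmianji", "拉伸面积",
        c(30, 120), 0, "cm2"),
    cat_("Leaf color", "yese", "叶色",
         c("darkgreen", "green", "lightgreen"),
         c("深绿", "绿色", "浅绿")),
    num("Yield", "chanliang", "产量", c(300, 620), 1, "kg/mu"),
    cat_("Plant type", "zhuxing", "株型",
         c("compact", "semicompact", "loose"),
         c("紧凑", "较紧凑", "松散")),
    cat_("Sowing time", "bozhongqi", "播种期",
         c("earlyoct", "midoct", "lateoct"),
         c("十月上旬", "十月中旬",
           "十月下旬")),
    num("Crude protein content", "cudanbai", "粗蛋白",
        c(11, 17), 1, "%"),
    num("Seeding quantity", "bozhongliang", "播种量",
        c(8, 15), 1, "kg/mu"),
    num("Wet gluten content", "shimianjin", "湿面筋",
        c(24, 38), 1, "%"),
    cat_("Disease susceptibility", "kangbingxing", "抗病性",
         c("resistant", "midresistant", "susceptible"),
         c("抗病", "中抗", "感病"))
  )
}

#' Synthetic-corpus configuration
#'
#' @param n_sentences total sentences generated across the three splits.
#' @param relations subset of the default relation schema to use
#'   (default: all 23).
#' @param tails_per_head integer range `c(min, max)` of attribute clauses
#'   per sentence; the minimum of 2 guarantees every sentence exhibits
#'   single-entity overlap.
#' @param distractor_rate probability that a sentence carries one
#'   unannotated numeric distractor clause (a unit-bearing number bound to
#'   no relation), exercising false-positive control.
#' @param lexicon_size total words in the emitted word-vector table
#'   (attribute keywords, units and trait words first, random fillers up
#'   to the requested size).
#' @param word_dim lexicon vector dimensionality.
#' @param split train/dev/test fractions (must sum to 1).
#' @param chinese generate Chinese template tokens instead of romanized
#'   ones.
#' @param seed fixes all randomness.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_sentences = 100L, relations = NULL,
                         tails_per_head = c(2L, 6L), distractor_rate = 0.3,
                         lexicon_size = 300L, word_dim = 200L,
                         split = c(train = 0.8, dev = 0.1, test = 0.1),
                         chinese = FALSE, seed = 1L) {
  if (n_sentences < 1L) stop("n_sentences must be >= 1")
  if (tails_per_head[1L] < 1L) stop("tails_per_head minimum must be >= 1")
  specs <- attribute_specs(chinese)
  labels <- vapply(specs, function(s) s$label, character(1L))
  if (is.null(relations)) relations <- labels
  if (length(relations) == 0L) stop("relation schema must be non-empty")
  missing <- setdiff(relations, labels)
  if (length(missing)) {
    stop("no generator template for relation(s): ",
         paste(missing, collapse = ", "))
  }
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  structure(list(n_sentences = as.integer(n_sentences),
                 relations = relations,
                 specs = specs[match(relations, labels)],
                 tails_per_head = as.integer(tails_per_head),
                 distractor_rate = distractor_rate,
                 lexicon_size = as.integer(lexicon_size),
                 word_dim = as.integer(word_dim),
                 split = split, chinese = chinese,
                 seed = as.integer(seed)),
            class = "synth_config")
}

fmt_num <- function(range, dec) {
  v <- stats::runif(1L, range[1L], range[2L])
  formatC(round(v, dec), format = "f", digits = dec)
}

build_sentence <- function(cfg) {
  prefixes <- variety_prefixes(cfg$chinese)
  head_txt <- paste0(sample(prefixes, 1L), if (cfg$chinese) "" else " ",
                     sample(100:999, 1L))
  kmax <- min(cfg$tails_per_head[2L], length(cfg$specs))
  k <- if (kmax > cfg$tails_per_head[1L]) {
    sample(cfg$tails_per_head[1L]:kmax, 1L)
  } else {
    cfg$tails_per_head[1L]
  }
  chosen <- sample(seq_along(cfg$specs), k)
  sep <- if (cfg$chinese) "，" else ", "
  kwsep <- if (cfg$chinese) "" else " "
  clauses <- vector("list", k)
  for (j in seq_len(k)) {
    sp <- cfg$specs[[chosen[j]]]
    val <- if (sp$type == "num") {
      paste0(fmt_num(sp$range, sp$dec), sp$unit)
    } else {
      sample(sp$cats, 1L)
    }
    clauses[[j]] <- list(text = paste0(sp$keyword, kwsep, val),
                         value = val, relation = sp$label, gold = TRUE)
  }
  has_distractor <- stats::runif(1L) < cfg$distractor_rate
  if (has_distractor) {
    dkw <- if (cfg$chinese) {
      sample(c("编号", "样本", "批次"), 1L)
    } else {
      sample(c("bianhao", "yangben", "pici"), 1L)
    }
    dval <- paste0(sample(100:999, 1L), sample(c("g", "cm", "kg/mu"), 1L))
    d <- list(text = paste0(dkw, kwsep, dval), value = dval,
              relation = NA_character_, gold = FALSE)
    pos <- sample(seq_len(k + 1L), 1L) - 1L
    clauses <- append(clauses, list(d), after = pos)
  }
  text <- paste0(head_txt, sep,
                 paste(vapply(clauses, `[[`, character(1L), "text"),
                       collapse = sep),
                 if (cfg$chinese) "。" else ".")
  head_sp <- span(0L, nchars_of(head_txt), text)
  triples <- list()
  cursor <- nchars_of(head_txt)
  for (cl in clauses) {
    cursor <- cursor + nchars_of(sep)
    clen <- nchars_of(cl$text)
    if (cl$gold) {
      vlen <- nchars_of(cl$value)
      vstart <- cursor + clen - vlen
      triples[[length(triples) + 1L]] <-
        triple(head_sp, cl$relation, span(vstart, vstart + vlen, text))
    }
    cursor <- cursor + clen
  }
  list(sentence = annotated_sentence(text, triples),
       has_distractor = has_distractor)
}

#' Generate a synthetic annotated corpus plus matching lexicon
#'
#' Produces train/dev/test splits of variety-report sentences, each with
#' one head entity and at least two attribute tails (single-entity
#' overlap), together with a random word-vector table covering every
#' attribute keyword, unit token and trait word appearing in the corpus
#' (so candidate-word matching can supply boundary cues such as "g/L"),
#' padded with random filler words. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list with `train`, `dev`, `test` (lists of
#'   [annotated_sentence()]), `lexicon` (a [word_vector_table()]),
#'   `schema` (character vector) and `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_sentences
  sents <- vector("list", n)
  for (i in seq_len(n)) sents[[i]] <- build_sentence(config)$sentence
  n_train <- round(config$split[["train"]] * n)
  n_dev <- round(config$split[["dev"]] * n)
  n_train <- max(0L, min(n, n_train))
  n_dev <- max(0L, min(n - n_train, n_dev))
  idx <- seq_len(n)
  lex_words <- corpus_lexicon_words(config)
  n_fill <- max(0L, config$lexicon_size - length(lex_words))
  fillers <- unique(replicate(n_fill + 10L, paste(
    sample(letters, sample(3:7, 1L), replace = TRUE), collapse = "")))
  fillers <- setdiff(fillers, lex_words)[seq_len(min(n_fill, n_fill + 10L))]
  fillers <- fillers[!is.na(fillers)]
  all_words <- c(lex_words, fillers)
  v <- matrix(stats::rnorm(length(all_words) * config$word_dim),
              length(all_words), config$word_dim)
  v <- v / sqrt(rowSums(v^2))
  lexicon <- word_vector_table(all_words, v)
  list(train = sents[idx <= n_train],
       dev = sents[idx > n_train & idx <= n_train + n_dev],
       test = sents[idx > n_train + n_dev],
       lexicon = lexicon,
       schema = config$relations,
       config = config)
}

# Domain words the lexicon must contain: attribute keywords, units,
# categorical trait words, variety-name prefixes.
corpus_lexicon_words <- function(config) {
  words <- character()
  for (sp in config$specs) {
    words <- c(words, sp$keyword)
    if (sp$type == "num") words <- c(words, sp$unit) else words <- c(words, sp$cats)
  }
  words <- c(words, variety_prefixes(config$chinese))
  unique(words[nzchar(words)])
}

#' Write a generated corpus to a directory
#'
#' Emits `train.jsonl`, `dev.jsonl`, `test.jsonl`, `vectors.txt`
#' (word2vec text format) and `schema.json`.
#'
#' @param corpus result of [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus_jsonl(corpus$train, file.path(dir, "train.jsonl"))
  write_corpus_jsonl(corpus$dev, file.path(dir, "dev.jsonl"))
  write_corpus_jsonl(corpus$test, file.path(dir, "test.jsonl"))
  write_word_vectors(corpus$lexicon, file.path(dir, "vectors.txt"))
  jsonlite::write_json(corpus$schema, file.path(dir, "schema.json"))
  invisible(dir)
}
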