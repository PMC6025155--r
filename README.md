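# kitm — Knowledge-Involved Topic Modeling for consumer health text

Patient-reported posts in online health communities (drug-review forums,
condition-specific support boards) are short, noisy narratives that carry
real medical content — drug names, side effects, conditions — buried in lay
language. `kitm` is an R package for mining that content with the help of a
medical terminology graph: it encodes post terms against a knowledge base
of concepts and typed relations, expands each post with *latent* concepts
reachable through the IS_A hierarchy, fits a Labeled LDA topic model over
the (optionally expanded) corpus, and scores everything with four
knowledge-rate metrics. It is aimed at health-informatics researchers who
want a self-contained, testable implementation of knowledge-involved topic
modeling without licensing or downloading a full terminology distribution.

## The model in brief

**Knowledge base.** A concept is `(code, relations, attributes,
definitions)` with a source vocabulary, preferred name, synonyms and a
semantic type. The hierarchy `KH` is the subgraph of relations labelled
`IS_A` (acyclicity enforced). Readers exist for UMLS-Metathesaurus-style
pipe-delimited files (MRCONSO/MRREL column conventions, configurable) and
for a self-contained toy TSV dialect (grammar below).

**Encoding.** Tokens are matched against the knowledge base by normalized
dictionary lookup (greedy longest match, up to 3 tokens); each match
carries the full quadruple set *(knowledge base, code, semantic type,
preferred name)* — ambiguity is preserved. Coarse part-of-speech tags come
from a built-in rule/lexicon tagger (no model downloads).

**Expansion.** For layer *z* = 1..*m*, every knowledge-base concept at
shortest-path distance exactly *z* from a post's explicit concepts is
appended to the post (bag-of-words augmentation over hierarchy edges by
default).

**Topic model.** Labeled LDA: one topic per label, and each document's
topic distribution has support *only* on its own labels. Inference is
zero-order collapsed variational Bayes (CVB0): token *i* in document *d*
with word *w* holds a variational distribution over the document's labels,
updated as

    gamma_i(k) ∝ (N_wk − gamma_i(k) + β) / (N_k − gamma_i(k) + Vβ) · (N_dk − gamma_i(k) + α)

Held-out quality is the document-completion perplexity
`b^(−(1/N) Σ log_b q(x_i))` (base-invariant; first half of each held-out
document folds in, second half is scored).

**Metrics.**

| metric | definition | meaning |
|---|---|---|
| EKR | `n_k / n_raw` | fraction of terms carrying knowledge-base concepts |
| LKR(m) | `(k_r − k_d) / k_d` | relative concept growth after *m* expansion layers |
| KCR | `n_s / n` | fraction of extracted relation triples corroborated by the KB |
| PK | `b^(−(1/N) Σ log_b q(x_i))` | held-out perplexity of the topic model |

## Worked example

Five example drug-review posts ship with the package together with a
miniature drug/condition ontology:

```r
library(kitm)
kb    <- load_toy_kb(system.file("extdata", "toy_kb.tsv", package = "kitm"))
posts <- example_posts()
p     <- posts$posts[["t2p4"]]          # the trazodone post
enc   <- encode_terms(tokenize(p$text), kb, post_id = p$id)
enc
#> <kitm_encoded 't2p4': 12 raw terms, 2 concept-bearing, 2 unique codes>
ekr(enc)                                 # 2 of 12 tokens are KB concepts
#> [1] 0.1666667
lkr(enc, kb, m = 1)                      # one hierarchy layer doubles the concept set
#> [1] 1
extract_relation_items(enc, kb)[, 1:4]
#>          kind source_code  relation_label target_code
#> 1 descriptive       D0004        adjacent       C0006
#> 2    semantic       D0004 associated_with       C0006
kcr(extract_relation_items(enc, kb), kb)
#> [1] 1
expand_text(enc, kb, m = 1)$latent_terms[[1]]
#> [1] "C0001" "D0001"
```

Reading: of the 12 tokens in the post, `trazodone` (D0004) and
`grogginess` (C0006) match the knowledge base, so EKR = 2/12. One
expansion layer reaches their parents `condition` (C0001) and `drug`
(D0001), doubling the concept set (LKR = 1). The two concepts are adjacent
in the text *and* related in the knowledge base, so both a descriptive and
a semantic relation item are extracted, and both endpoints are related in
the KB, giving KCR = 1.

A full corpus run (tokenize → filter → encode → expand → train →
evaluate, with a JSON manifest of per-stage counts and artifact hashes):

```r
cfg <- run_config(system.file("extdata", "table2_posts.csv", package = "kitm"),
                  system.file("extdata", "toy_kb.tsv", package = "kitm"),
                  out_dir = "out",
                  pipeline = pipeline_config(term_min_doc_count = 1,
                                             label_min_doc_count = 1,
                                             stoplist_size = 0,
                                             doc_min_length = 1),
                  n_iterations = 20)
man <- run_pipeline(cfg)
man$counts$docs_modeled
#> [1] 5
```

(The canonical filter thresholds — terms ≥ 3 characters, in ≥ 4 documents,
a 30-term dynamic stoplist, documents ≥ 5 terms, labels in ≥ 10 documents —
are the defaults of `pipeline_config()`; a 5-post corpus only survives
permissive settings.)

A command-line front end covering `synth`, `preprocess`, `encode`,
`expand`, `train`, `topics`, `evaluate` and `run` is installed at
`system.file("cli", "kitm.R", package = "kitm")`.

## Toy knowledge-base TSV grammar

```
file      := "#KB" SP name NL sections
sections  := "#CONCEPTS" NL concept* ("#RELATIONS" NL relation*)?
concept   := code TAB source TAB preferred_name [TAB synonyms [TAB semantic_type]] NL
synonyms  := term (";" term)*
relation  := source_code TAB label TAB target_code NL
comment   := "//" ... NL          (ignored, as are blank lines)
```

Codes must be unique; relation endpoints must resolve; `IS_A` edges must
be acyclic. `inst/extdata/mini_mrconso.rrf` / `mini_mrrel.rrf` are
*synthetic* miniature files in the pipe-delimited layout (real
terminology distributions are licensed products and are not bundled).

## Limitations

- Concept recognition is dictionary lookup: no word-sense disambiguation,
  negation detection, spelling correction or stemming.
- The part-of-speech tagger is deliberately coarse (six tags).
- No Gibbs sampler or online variational inference; CVB0 only.
- The synthetic generator emulates the Labeled LDA generative story, not
  real forum language; see the methods vignette for what green tests do
  and do not establish.
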