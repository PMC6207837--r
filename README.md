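# nssanchor

Morphological descriptions in biodiversity literature are full of *non-specific
structure* (NSS) terms — part words such as *apex*, *base*, *margin*, *side* or
*surface* that do not denote an identifiable organ on their own. A character
like *apex acuminate* is only useful once the apex is anchored to its parent
organ (*leaf apex acuminate*). Linguistically this is a mereological bridging
reference: the NSS mention must be linked to the discourse entity it is *part
of*, which may precede or follow it. `nssanchor` resolves these references in
pre-annotated statements and is aimed at people building phenotype-annotation
and character-extraction pipelines over taxonomic text.

Formally: given a statement `W = {w_1, ..., w_n}` with entity mentions and a
set of NSS mentions `A = {a_1, ..., a_k}` in `W`, find for each `a_j` the
entity `w_k` such that `(a_j, w_k)` is the intended part-of relation. The
package implements four resolvers plus an evaluation harness:

* **Syntactic rule engine** — rules ordered by confidence (of-phrase >
  possession words > a three-sentence window), every candidate filtered by a
  *soft* part-of ontology (an edge `apex part_of leaf` means an apex *could*
  belong to a leaf; subclass edges such as `elytron side ⊑ side` are expanded
  transitively on both sides of a query). Chained NSS anchors are resolved
  recursively with compound naming: in *"abdomen has a thin edge at its upper
  margin"*, *edge* anchors to *upper margin*, which anchors to *abdomen*, so
  *edge*'s final anchor is **abdomen upper margin**. An `ontology_only`
  variant drops the syntactic rules and keeps window + ontology.
* **Pairwise SVM** — every (candidate, NSS) pair is scored by a
  probability-estimating SVM (polynomial kernel, degree 3, positive class
  weight 7) over distance/position features, connector + bag-of-words
  features, and semantic features (ontology membership, candidate-is-NSS);
  the anchor is `argmax_x Pr(x, nss)`. A `feature_groups = c(1, 2)` variation
  omits the semantic group.
* **Two baselines** — always the subject (first) entity; always the closest
  entity.
* **Evaluation** — micro-averaged `P = |S∩H|/|S|`, `R = |S∩H|/|H|`, and their
  harmonic mean F1 over pooled NSS occurrences, plus the error-overlap
  partition (wrong under A only / B only / both) for comparing two methods.

Because annotated corpora for this task are rarely distributable, the package
ships a deterministic synthetic generator (`generate_corpus()`) that emits
schema-valid statements with planted of-phrase, possession, window and
chained-NSS signals, a matching ontology, gold anchors and a provenance log.

## Worked example

```r
library(nssanchor)

we <- worked_examples()          # the two classic statements + minimal ontology
print(we$statements[[1]])
#> <nss_statement 'leaflet-example': 42 tokens, 12 entities (6 NSS), 2 relations, 6 gold>
#>   Leaflets articulated , inserted near the edges of the rhachis towards the
#>   adaxial side , lacking a differently coloured basal gland ; stomata on lower
#>   surface only or on both surfaces ; epidermal cells elongated parallel to
#>   long axes of leaflets .

res <- resolve_statement(we$statements[[1]], we$ontology)
res[, c("nss_name", "anchor_name", "detail")]
#>        nss_name anchor_name    detail
#> 1         edges     rhachis of_phrase
#> 2  adaxial side    leaflets    window
#> 3 lower surface    leaflets    window
#> 4      surfaces    leaflets    window
#> 5         cells   epidermal    window
#> 6     long axes    leaflets of_phrase

score(res, we$statements[1])
#> <nss_eval_report: |H| = 6, |S| = 6, correct = 6>
#>   P = 100.0%  R = 100.0%  F1 = 100.0%
```

*edges* is resolved through the of-phrase *"edges of the rhachis"*; the other
mentions fall back to the window rule, where the ontology licence (`side
part_of leaflet`, `surface part_of leaflet`, ...) selects the right organ among
the nearby entities. The subject baseline would link *edges* to *leaflets*, the
closest-entity baseline to *rhachis*:

```r
baseline_subject(we$statements[[1]])$anchor_name[1]   # "leaflets"
baseline_closest(we$statements[[1]])$anchor_name[1]   # "rhachis"
```

A full pipeline on synthetic data:

```r
co <- generate_corpus(generator_config(n_statements = 200, seed = 7))
score(resolve_corpus(co$statements, co$ontology), co$statements)$f1   # 100
model <- train_svm(co$statements[1:130], co$ontology, svm_config())
score(predict(model, co$statements[131:200], co$ontology),
      co$statements[131:200])$f1
```

The same steps are available from a shell through the installed
`exec/nssanchor` script (`make-fixtures`, `resolve`, `train-svm`, `evaluate`).

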