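---
title: "Methods: PPI article triage with word and syntactic features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PPI article triage with word and syntactic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppitriage)
```

## The problem

Curators of protein–protein interaction (PPI) databases must find, among
millions of Medline abstracts, the small fraction that report physical
interactions. ppitriage implements a document-level classifier for this
triage step. The pipeline is: detect gene/protein names with a statistical
Priority Model; extract word features (n-grams, character substrings, MeSH
descriptor subphrases) and syntactic features (dependency relations with
gene-name anonymization); optionally induce higher-order conjunction
features from the loss gradient on misclassified training documents; and
fit a large-margin linear classifier under the modified Huber loss. The
classifier emits real-valued scores for ranking and sign-binarized labels
for classification.

## The Priority Model

Gene names are recognized by a token-level language model in which tokens
further to the *right* of a name dominate its classification — "insulin
receptor" is a receptor, not an insulin. Each token $t$ carries two
probabilities: $p_t$, the probability that $t$ indicates the gene class,
and $q_t$, the probability that $t$ is a more reliable indicator than any
token to its left. A name $t_1 \dots t_k$ scores

$$\Pr(\text{gene}) \;=\; \sum_{i=1}^{k} \lambda_i \, p_{t_i},
\qquad
\lambda_i \;=\; q'_i \prod_{j>i} (1 - q_{t_j}),$$

where $q'_i = q_{t_i}$ except that the leftmost token has $q'_1 \equiv 1$.
The weights telescope to 1, so the score is a convex combination of the
tokens' $p$ values: it always lies between the smallest and largest $p$
in the name, equals $p$ for a single token, and is dominated by the
rightmost reliable token. An equivalent recursive reading — the rightmost
token decides with probability $q$, otherwise the prefix decides — is used
as the brute-force oracle in the tests. Fixing the leftmost $q'$ to 1 is
our normalization choice; it is what guarantees the weights sum to one for
every $q$ configuration.

Training maximizes the Bernoulli likelihood of gene/non-gene name lists in
logit parameterization, starting from all logits zero, with BFGS and
analytic gradients; fitted probabilities are clipped to
$[10^{-6}, 1-10^{-6}]$ so tokens seen in only one class stay finite.
Tagging scores candidate phrases (a pluggable chunker; the built-in
fallback proposes maximal runs of capitalized or digit-bearing tokens) and
accepts a candidate when its score exceeds the decision threshold
(default 0.5) — except that a purely numeric string is never a gene name.
Overlapping accepted candidates resolve leftmost-longest, and a multi-word
mention then behaves as a single unit downstream.

## Features

All features are binary presence indicators, namespaced by family prefix
(`W1|`, `W2|`, `W3|`, `S|`, `M1|`, `M2|`, `D|`, `H|`) so families cannot
collide:

* **Word n-grams** over lowercased tokens, within sentences only (the
  title and the abstract are treated as separate sentences, and n-grams
  never cross a sentence boundary). When gene anonymization is on, each
  detected mention is collapsed to a single `PTNWORD` token before n-gram
  extraction, so multi-word names occupy one slot.
* **Character substrings**: all contiguous windows of `substring_k`
  characters within each token (default 6, the length that worked best in
  development); shorter tokens contribute themselves whole. Windows never
  cross token boundaries, and substrings are taken from the raw tokens,
  not the anonymized stream — substrings of the tag would carry no signal.
* **MeSH subphrases**: each descriptor is lowercased and tokenized;
  unigrams and within-descriptor bigrams are emitted. Qualifiers after
  `/` count as separate descriptors (included by default; the choice is
  ours, made once).
* **Dependency relations** `D|rel(head,dep)` from externally supplied
  parses (parsing itself is pluggable input, not computed here). When
  anonymization is on, a *dependent* word inside a detected mention is
  replaced by the tag; head words are never anonymized. With stemming on,
  the Porter (1980) stemmer — implemented in full in `R/porter.R` — is
  applied to the head and to a non-anonymized dependent; the tag itself is
  never stemmed, and stemming applies only to this family.
* **Higher-order conjunctions** `H|i&j`, active iff both constituent
  features are active (see below).

The vocabulary is fitted on training documents only: features seen in
fewer than `min_doc_freq` documents are cut (default 4 in the richer run
configurations; 1 disables the cut), survivors are indexed
lexicographically, and the vocabulary is frozen — unknown features at
predict time are dropped. We read the frequency cut as *document*
frequency since features are per-document binary indicators.

## The classifier

With binary feature vectors $X_i$ and labels $y_i \in \{+1,-1\}$, training
minimizes

$$C(w, \theta) = \sum_{i=1}^{T} h\!\big(y_i (w \cdot X_i + \theta)\big)
  + \lambda \lVert w \rVert^2,
\qquad
h(z) = \begin{cases}
  -4z & z < -1 \\
  (1-z)^2 & -1 \le z < 1 \\
  0 & z \ge 1,
\end{cases}$$

the modified Huber loss: convex, continuously differentiable, quadratic
near the margin and linear for badly misclassified points. The
regularization weight is derived from the data,
$\lambda = \lambda' \langle |x| \rangle^2$ with
$\langle |x| \rangle$ the mean Euclidean norm of the training vectors
(for binary vectors, the square root of the active-feature count) and
$\lambda' = 0.0005$ by default. Alternate normalizations (mean instead of
summed loss; $\lambda$ divided by $T$) are switchable via arguments but
are not the defaults.

Optimization is deterministic full-batch gradient descent from
$w = 0, \theta = 0$ with backtracking line search under an Armijo
sufficient-decrease condition; the step size re-grows after each accepted
iteration. Descent stops at a relative cost-change tolerance
(default $10^{-8}$) or the iteration cap (default 500). The cost trace is
non-increasing by construction and the fit is invariant to example order.
Scores are $w \cdot x + \theta$ (higher = more PPI-like, used directly for
ranking); binary labels are the score sign, with an exact zero mapped to
$-1$ so an uncommitted document is not flagged as relevant.

## Higher-order feature induction

One induction round (the default; more are configurable): (1) collect the
training documents the fitted model misclassifies; (2) for every unordered
pair of features co-active in such a document, accumulate
$h'(z_d)\, y_d$ — the gradient of the document's loss with respect to a
conjunction feature whose weight is still zero — over the misclassified
documents, counting occurrences; (3) keep pairs occurring at least $a$
times with $|{\textstyle\sum} \partial h| \ge b$ (both inclusive;
defaults $a = 4$, $b = 340$), append them to the vocabulary as AND
features, and retrain. The derivative-sum threshold scales with corpus
size, so small corpora need a proportionally smaller $b$; the synthetic
recovery tests use $b = 1$ at $n = 200$. Pairs are allowed across feature
families, and the summation runs over the misclassified documents only —
both choices ours, made once and fixed.

## Evaluation

`evaluate_scores()` computes the full suite from a score table and gold
labels: the confusion counts; accuracy, specificity, sensitivity,
precision (a zero denominator yields NaN with a warning); F1
$= 2PR/(P+R)$; Matthews correlation
$(TP \cdot TN - FP \cdot FN)/\sqrt{(TP{+}FP)(TP{+}FN)(TN{+}FP)(TN{+}FN)}$
(0 when any factor is zero); average precision (the mean of precision at
the relevant documents' ranks — the non-interpolated P/R area);
interpolated P/R area, where interpolated precision at recall $r$ is the
maximum precision at any recall $\ge r$, averaged at the positives'
recall points (a trapezoidal alternative sits behind a flag); and
precision at ranks 100/200/300 when the list is long enough. Rankings are
deterministic: descending score, ties broken by ascending document id.

## The synthetic corpus

Real triage corpora are external and large, so the package ships a
generator whose output exercises every pipeline stage. Positive documents
contain at least one trigger sentence `<GENE> <trigger> <GENE>`
("interacts with", "binds", "phosphorylates", ...); negatives use neutral
verbs in the same frame. Gene-like tokens come from a synthetic lexicon of
mixed-case stems with digit suffixes; MeSH descriptors are drawn
label-conditionally with a shared pool; background tokens are
label-independent noise; and every sentence carries a template parse —
`(subj, verb, gene1)`, `(obj, verb, gene2)` — plus a gold mention map of
every planted gene span. Labels are assigned deterministically by index
(the first $\lceil \text{pos\_fraction} \cdot n \rceil$ documents are
positive) so class counts are exact; only token content is random, and
the whole corpus is a pure function of the seed.

Defaults, chosen once: 400 documents, half positive (mirroring the roughly
balanced training corpora of this task, as opposed to its skewed test
sets), a 200-word background vocabulary, 5 trigger phrases, one extra
gene token per filler sentence in expectation, and 3 background noise
tokens per sentence. Under these conditions the planted signal is strong:
a run1-configuration model reaches held-out accuracy and average precision
near 1 at $n = 400$. That is what the recovery tests are for — they show
the pipeline finds planted structure, not that real abstracts are this
easy. The generator does not emulate the hard parts of real triage:
lexical ambiguity between gene names and common words, interactions
described across sentences, parser errors, or the 85%-negative class skew
of a realistic test stream.

## Numerical and design notes

* Priority scores are clipped to $[10^{-6}, 1-10^{-6}]$ inside the
  likelihood; the unseen-token defaults are $p = q = 0.5$
  (uninformative), since no smoothing rule is prescribed.
* The tokenizer keeps internal hyphens and digits ("MEK-1", "p53" stay
  single tokens) and splits sentences at `.?!` + space + uppercase.
* If backtracking cannot find sufficient decrease but the cost does not
  increase, the fit is declared stationary and returns; a genuine cost
  increase after exhausting backtracking is an error.
* Degenerate inputs: an empty candidate list tags nothing; a document
  with no in-vocabulary features legally vectorizes to the empty set and
  scores exactly $\theta$; an all-empty training set yields
  $\lambda = 0$ with a warning; single-class training data is an error.
* Problem sizes in the tests (corpora of 10–400 documents, vector sets of
  15–200, rankings of length 20) are chosen so each check isolates one
  property at the smallest scale where it is informative.

## Known limitations

Mention matching for anonymization joins parses to mentions by surface
string within a sentence, because parse rows carry words rather than token
indices; a gene token that also occurs as a non-gene word in the same
sentence would be over-anonymized. The regex candidate chunker is a crude
stand-in for a noun-phrase chunker and over-proposes capitalized
non-names; the Priority Model's score threshold is what filters them. No
TF or TF-IDF weighting is offered (features are presence-only by design),
there are no kernels or minibatch training, and scores are not calibrated
to probabilities.
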