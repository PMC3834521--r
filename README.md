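# analogynet

Connectionist simulations of forced-choice verbal analogy
(A:B::C:[D1|D2]) for computational cognitive scientists studying how
relational responding develops from associative beginnings, and how it
breaks down after frontal or anterior-temporal damage (the two variants
of frontotemporal lobar degeneration, FTLD).

## The model

A recurrent network with four pools of logistic units — localist
first-role items (A), localist second-role items (B), a 128-unit
distributed relation pool (R) and a hidden integrating pool (H) — is
trained by backpropagation through time to complete item–relation–item
propositions given any two of the three elements. Unclamped activations
follow

    a(t) = a(t-1) + lambda * (sigma(net(t)) - a(t-1))

with a fixed hidden bias of −2. Relations are instances of 8 disjoint
16-unit prototypes (two units turned off per instance), so relations can
be *similar* without being identical. The training corpus is a
counterbalanced set of proposition *cells*: one source A:R1:B, one
relational target C:R1′:D1 (same prototype as the source), and weak /
moderate / strong foils C:R2..4:D2..4 trained 1 / 3 / 9 times per epoch.
Each cell yields three analogy questions whose semantic facilitation
index (SFI) is positive, zero or negative according to whether the foil
is less, equally or more associated with C than the correct answer.

Questions are answered without any analogy training, by a *twin*
architecture: two weight-identical copies of the network (A,B,H1 /
C,D,H2) share the relation pool, each half's hidden-to-relation drive is
halved, and each candidate D is clamped briefly and then released — the
candidate whose unit keeps the stronger "echo" of activation wins.
Frontal damage is modelled as dropping the H1 bias from −2 to −6.5
(context maintenance lost; association returns); temporal damage as
deleting each learned connection with probability 0.42, identically in
both halves (pattern completion degraded across the board).

## Worked example

```r
library(analogynet)

env <- build_environment(environment_config(seed = 1))
env
#> <analogy_environment> 40 cells in 8 groups
#>   40 first-role and 40 second-role items, 200 relation instances
#>   200 propositions (2280 trials/epoch), 120 analogy questions

net <- init_network(network_config_for(env, seed = 1))
net <- train_network(net, env, epochs = 350, questions = env$questions,
                     eval_every = 50, seed = 11)
evaluate_analogies(build_twin(net), env$questions)
#> # A tibble: 4 x 3
#>   sfi_label     n accuracy
#>   <chr>     <int>    <dbl>
#> 1 positive     40    0.975
#> 2 zero         40    1
#> 3 negative     40    0.8
#> 4 overall     120    0.925
```

The untrained network answers at chance; the trained one is near
ceiling except on negative-SFI questions, where a strongly associated
foil opposes the relationally correct answer. The full developmental
study and the lesion study:

```r
sim <- simulation1(seed = 1)       # 5 networks x 350 epochs, ~10 min
sim
#> <analogy_sim1> 5 networks, 350 epochs
#>   final accuracy: positive 0.950, zero 0.980, negative 0.835
#>   negative-SFI sustained above chance from epoch 70
autoplot(sim)                      # developmental curves by SFI type

les <- simulation2(sim, seed = 1)  # control / frontal / 25 temporal
les
#> <analogy_sim2> condition means:
#>  condition accuracy_positive accuracy_zero accuracy_negative accuracy_overall sfi_effect
#>    control             0.950         0.980             0.835            0.922      0.115
#>    frontal             0.765         0.610             0.390            0.588      0.375
#>   temporal             0.665         0.614             0.537            0.605      0.128
autoplot(les)                      # grouped bars by condition and SFI
```

Early in training the negative-SFI curve dips well below chance (the
associative phase), then crosses chance for good around epoch 70 and
converges — the relational shift. After the frontal lesion the SFI
effect (positive − negative accuracy) more than triples while
positive-SFI questions are hurt least; after the temporal lesion all
three question types degrade together.

A thin command-line front end over the same functions is installed at
`inst/cli/analogynet` (`gen-env`, `sim1`, `sim2` subcommands).

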