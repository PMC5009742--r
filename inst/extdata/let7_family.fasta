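>let-7a
UGAGGUAGUAGGUUGUAUAGUU
>let-7b
UGAGGUAGUAGGUUGUGUGGUU
>let-7c
UGAGGUAGUAGGUUGUAUGGUU
>let-7d
AGAGGUAGUAGGUUGCAUAGUU
>let-7e
UGAGGUAGGAGGUUGUAUAGUU
>let-7f
UGAGGUAGUAGAUUGUAUAGUU
>let-7g
UGAGGUAGUAGUUUGUACAGUU
>let-7i
UGAGGUAGUAGUUUGUGCUGUU
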