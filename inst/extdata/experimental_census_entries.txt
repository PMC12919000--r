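2kjh
3a33
3ugb
4auq
4v3k
4whv
5bnb
5d0k
5d0m
5dfl
5eya
5h7s
5ifr
5tut
5ulf
5ulh
5ulk
5vzw
5zbu
6jb6
6jb7
6s53
6t7f
6w9d
7ai0
7ai1
7zj3
8ams
8eb0
8grm
8pjn
8r5h
8rx0
9yea
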