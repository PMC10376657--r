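[{"id":"CH01","x":0.1,"y":0.1},{"id":"CH02","x":0.26,"y":0.1},{"id":"CH03","x":0.42,"y":0.1},{"id":"CH04","x":0.58,"y":0.1},{"id":"CH05","x":0.74,"y":0.1},{"id":"CH06","x":0.9,"y":0.1},{"id":"CH07","x":0.1,"y":0.26},{"id":"CH08","x":0.26,"y":0.26},{"id":"CH09","x":0.42,"y":0.26},{"id":"CH10","x":0.58,"y":0.26},{"id":"CH11","x":0.74,"y":0.26},{"id":"CH12","x":0.9,"y":0.26},{"id":"CH13","x":0.1,"y":0.42},{"id":"CH14","x":0.26,"y":0.42},{"id":"CH15","x":0.42,"y":0.42},{"id":"CH16","x":0.58,"y":0.42},{"id":"CH17","x":0.74,"y":0.42},{"id":"CH18","x":0.9,"y":0.42},{"id":"CH19","x":0.1,"y":0.58},{"id":"CH20","x":0.26,"y":0.58},{"id":"CH21","x":0.42,"y":0.58},{"id":"CH22","x":0.58,"y":0.58},{"id":"CH23","x":0.74,"y":0.58},{"id":"CH24","x":0.9,"y":0.58},{"id":"CH25","x":0.1,"y":0.74},{"id":"CH26","x":0.26,"y":0.74},{"id":"CH27","x":0.42,"y":0.74},{"id":"CH28","x":0.58,"y":0.74},{"id":"CH29","x":0.74,"y":0.74},{"id":"CH30","x":0.9,"y":0.74},{"id":"CH31","x":0.1,"y":0.9},{"id":"CH32","x":0.26,"y":0.9},{"id":"CH33","x":0.42,"y":0.9},{"id":"CH34","x":0.58,"y":0.9},{"id":"CH35","x":0.74,"y":0.9},{"id":"CH36","x":0.9,"y":0.9}]
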